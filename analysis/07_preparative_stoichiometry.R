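#!/usr/bin/env Rscript
# Stage 7 -- preparative-scale stoichiometry.
#
# Reproduces the arithmetic of the semi-preparative syntheses: catalyst
# loading in mol%, donor fold-excess, and molar yields from the isolated
# masses (with the 6% w/w contaminant correction where it applies),
# alongside the printed values they should match.

suppressPackageStartupMessages(library(mutscape))
dir.create("results", showWarnings = FALSE)

message(sprintf("catalyst loading: 14.7 uM on 2 mM -> %.1f mol%%; 29.4 uM -> %.1f mol%%",
                catalyst_molpercent(14.7, 2), catalyst_molpercent(29.4, 2)))
message(sprintf("donor fold-excess: 50 mM over 2 mM -> %g-fold",
                fold_excess(50, 2)))

report <- prep_scale_report()
readr::write_csv(report, "results/preparative_yields.csv")
dev_mmol <- max(abs(report$mmol - report$printed_mmol))
dev_pct <- max(abs(report$percent - report$printed_percent))
message(sprintf("%d preparative reactions recomputed; largest deviation from print: %.4f mmol / %.1f%%",
                nrow(report), dev_mmol, dev_pct))
print(as.data.frame(report[report$product %in% c("6a", "7"),
                           c("product", "catalyst", "mass_mg", "mmol",
                             "percent", "printed_percent")]),
      digits = 3)
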