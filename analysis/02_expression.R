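#!/usr/bin/env Rscript
# Stage 2 -- soluble-expression landscape by gel densitometry.
#
# Each gel's calibration lanes give a per-gel standard curve (never
# applied across gels); sample-lane intensities are inverted to mg/ml of
# soluble protein in the CFE, with concentrations under 0.5 mg/ml flagged
# below the detection limit. Outputs: the expression landscape (long CSV)
# and the per-substitution average effect.

suppressPackageStartupMessages(library(mutscape))

dataset_dir <- "scratch/dataset"
config <- readRDS(file.path(dataset_dir, "config.rds"))
reference <- load_reference(file.path(dataset_dir, "reference.fasta"))
manifest <- readr::read_csv(file.path(dataset_dir, "manifest.csv"),
                            comment = "#", show_col_types = FALSE)
gels <- readr::read_csv(file.path(dataset_dir, "gels.csv"),
                        comment = "#", show_col_types = FALSE)

expression <- quantify_gel(gels, loaded_volume_ul = config$gel$loaded_volume_ul,
                           lod_mg_ml = config$gel$lod_mg_ml)
message(sprintf("quantified %d variants on %d gels (mean calibration R2 = %.3f)",
                nrow(expression), length(unique(expression$gel_id)),
                mean(expression$r_squared[!duplicated(expression$gel_id)])))
message(sprintf("%d variants below the %.1f mg/ml detection limit",
                sum(expression$below_lod), config$gel$lod_mg_ml))
readr::write_csv(expression, "results/expression.csv")

idx <- match(expression$variant_id, manifest$variant_id)
records <- tibble::tibble(position = manifest$position[idx],
                          mut_aa = manifest$mut_aa[idx],
                          state = ifelse(expression$below_lod, "below_lod",
                                         "value"),
                          value = expression$conc_mg_ml)
ls_expr <- assemble_landscape(records, "expression", manifest, reference,
                              wt_value = config$truth$wt_conc_mg_ml)
write_landscape_csv(ls_expr, "results/landscape_expression.csv")
print(ls_expr)

averages <- substitution_averages(ls_expr)
readr::write_csv(averages, "results/substitution_averages.csv")
worst <- averages[order(averages$mean_value), ][1:3, ]
message("least-tolerated substitutions on average: ",
        paste(sprintf("%s (%.2f mg/ml)", worst$mut_aa, worst$mean_value),
              collapse = ", "))
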