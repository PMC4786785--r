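#!/usr/bin/env Rscript
# Stage 6 -- focused combinatorial library and additivity predictions.
#
# The activity landscape's hotspot positions seed a focused library:
# limited degeneracy at three positions plus a fully degenerate NNK codon
# at the fourth, 1,600 protein variants in all. The enumerated manifest
# is written for in-silico screening, and the multiplicative additivity
# heuristic predicts combined-mutant effects from the measured singles.

suppressPackageStartupMessages(library(mutscape))

reference <- load_reference()
dir.create("results", showWarnings = FALSE)

design <- list(`6` = c("H", "I", "L", "M", "V"),
               `33` = c("A", "D", "E", "Q"),
               `45` = "NNK",
               `50` = c("F", "V", "L", "A"))
nnk <- expand_codon("NNK")
message(sprintf("NNK encodes %d amino acids over %d codons (%d stop)",
                length(nnk$amino_acids), nnk$n_codons, nnk$n_stop))
size <- library_size(design)
message("library size: ", size, " protein variants")

lib <- enumerate_library(design, reference)
stopifnot(nrow(lib) == size)
readr::write_csv(lib, "results/focused_library.csv")

# additivity predictions from the measured single effects, when available
singles_path <- "results/recovery_per_variant.csv"
if (file.exists(singles_path)) {
  est <- readr::read_csv(singles_path, show_col_types = FALSE)
  singles <- stats::setNames(est$est_rel, est$variant_id)
  combos <- lib$variant_id[lib$n_mutations >= 2]
  parts <- strsplit(combos, "/", fixed = TRUE)
  ok <- vapply(parts, function(p) all(p %in% names(singles)), logical(1))
  pred <- vapply(parts[ok], function(p) {
    as.numeric(predict_combined(singles, p))
  }, numeric(1))
  out <- tibble::tibble(variant_id = combos[ok], predicted_fold = pred,
                        model = "log_additive")
  readr::write_csv(out, "results/combined_predictions.csv")
  message(sprintf("predicted %d multi-mutants; best predicted fold %.1f (%s)",
                  nrow(out), max(out$predicted_fold),
                  out$variant_id[which.max(out$predicted_fold)]))
} else {
  message("single-mutant estimates not found; run stages 3 and 5 first")
}
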