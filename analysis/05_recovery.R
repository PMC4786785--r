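#!/usr/bin/env Rscript
# Stage 5 -- recovery audit against the generator's ground truth.
#
# Because the screen is simulated, every estimate can be compared with
# the value it should have recovered: expression concentrations, relative
# specific activities and e.r. values. This quantifies the error budget
# of the whole chain at the default noise levels.

suppressPackageStartupMessages(library(mutscape))

dataset_dir <- "scratch/dataset"
truth <- readr::read_csv(file.path(dataset_dir, "truth.csv"),
                         comment = "#", show_col_types = FALSE)
result <- list(
  expression = readr::read_csv("results/expression.csv",
                               show_col_types = FALSE),
  activity = readr::read_csv("results/activity.csv", show_col_types = FALSE),
  stereo = readr::read_csv("results/stereo.csv", show_col_types = FALSE))

metrics <- recovery_metrics(result, truth)
readr::write_csv(metrics, "results/recovery.csv")
message(sprintf(
  "median |error|: expression %.2f%%, relative activity %.2f%%, e.r. %.2f points",
  100 * metrics$expr_median_rel_err, 100 * metrics$activity_median_rel_err,
  metrics$er_median_abs_err_pp))

# per-variant table for closer inspection
act <- result$activity[result$activity$role == "variant" &
                         result$activity$state == "value", ]
i <- match(act$variant_id, truth$variant_id)
per_variant <- tibble::tibble(variant_id = act$variant_id,
                              true_rel = truth$true_rel_activity[i],
                              est_rel = act$relative)
readr::write_csv(per_variant, "results/recovery_per_variant.csv")
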