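#!/usr/bin/env Rscript
# Stage 3 -- relative-activity landscape from plate kinetics.
#
# Per plate: duplicate variant traces are pointwise-averaged, initial
# rates come from the best linear window in the early (<= 20% depleted)
# region, the mean empty-vector rate is subtracted, rates convert to
# specific activities via the expression measurements, and everything is
# normalized to the mean wild-type specific activity of that same plate.
# Outputs: activity records, the relative-activity landscape, the >5-fold
# hotspot report and a per-position classification summary.

suppressPackageStartupMessages(library(mutscape))

dataset_dir <- "scratch/dataset"
config <- readRDS(file.path(dataset_dir, "config.rds"))
reference <- load_reference(file.path(dataset_dir, "reference.fasta"))
manifest <- readr::read_csv(file.path(dataset_dir, "manifest.csv"),
                            comment = "#", show_col_types = FALSE)
plates <- readr::read_csv(file.path(dataset_dir, "plates.csv"),
                          comment = "#", show_col_types = FALSE)
expression <- readr::read_csv("results/expression.csv",
                              show_col_types = FALSE)

t0 <- Sys.time()
activity <- dplyr::bind_rows(lapply(split(plates, plates$plate_id),
                                    function(p) {
  analyze_plate(p, config$assay, expression,
                wt_conc_mg_ml = config$truth$wt_conc_mg_ml,
                min_points = config$rates$min_points,
                max_fraction_depleted = config$rates$max_fraction_depleted)
}))
message(sprintf("fitted %d wells on %d plates in %.1f s",
                nrow(activity), length(unique(activity$plate_id)),
                as.numeric(Sys.time() - t0, units = "secs")))
readr::write_csv(activity, "results/activity.csv")

var <- activity[activity$role == "variant", ]
idx <- match(var$variant_id, manifest$variant_id)
records <- tibble::tibble(position = manifest$position[idx],
                          mut_aa = manifest$mut_aa[idx],
                          state = var$state, value = var$relative)
ls_act <- assemble_landscape(records, "relative_activity", manifest,
                             reference)
write_landscape_csv(ls_act, "results/landscape_activity.csv")
print(ls_act)

hotspots <- find_hotspots(ls_act, config$thresholds$hotspot_fold)
readr::write_csv(hotspots, "results/hotspots.csv")
message(sprintf("%d cells above the %g-fold hotspot threshold at positions: %s",
                nrow(hotspots), config$thresholds$hotspot_fold,
                paste(unique(hotspots$position), collapse = ", ")))

summary <- position_summary(ls_act,
                            beneficial = config$thresholds$beneficial,
                            detrimental = config$thresholds$detrimental)
readr::write_csv(summary, "results/position_summary.csv")
message("positions with beneficial (>", config$thresholds$beneficial,
        "-fold) mutations: ",
        paste(summary$position[summary$n_beneficial > 0], collapse = ", "))
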