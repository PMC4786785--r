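#!/usr/bin/env Rscript
# Stage 1 -- simulate the full screening campaign.
#
# Generates, under the study's working conditions, everything the wet-lab
# screen would have produced: a 1,040-member single-mutant collection
# (>= 15 of 19 substitutions per position, Ile-2..Arg-62), densitometry
# gels with 0.5/1/2.5/5 ug calibration lanes, duplicate-well progress
# curves with wild-type and empty-vector controls on every plate, and one
# pooled chiral chromatogram per variant. Raw data are large and land in
# scratch/; the manifest is copied to results/ for reference.

suppressPackageStartupMessages(library(mutscape))

dataset_dir <- "scratch/dataset"
dir.create("results", showWarnings = FALSE)

config <- default_config(seed = 101L)
message("simulating dataset under ", dataset_dir, " (seed ", config$seed, ")")
t0 <- Sys.time()
run_simulate(config, dataset_dir)
message(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))

manifest <- readr::read_csv(file.path(dataset_dir, "manifest.csv"),
                            comment = "#", show_col_types = FALSE)
readr::write_csv(manifest, "results/manifest.csv")
cov <- coverage(manifest)
message(sprintf("collection: %d variants, %.2f%% of all possible singles (%d%% reported)",
                nrow(manifest), cov$percent, cov$rounded))
saveRDS(config, file.path(dataset_dir, "config.rds"))
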