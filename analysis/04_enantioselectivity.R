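#!/usr/bin/env Rscript
# Stage 4 -- enantioselectivity landscape from chiral HPLC.
#
# Each variant's pooled chromatogram is baseline-corrected, its four
# stereoisomer peaks integrated by the trapezoidal rule and assigned by
# retention-time window; the syn pair gives the e.r. (2R3S:2S3R) and the
# syn:anti split the d.r. Variants whose total peak area is too small for
# an adequate UV signal are flagged rather than valued. Outputs: stereo
# records, the e.r. landscape and the inversion report (majority
# enantiomer flipped versus wild type's 2R3S preference).

suppressPackageStartupMessages(library(mutscape))

dataset_dir <- "scratch/dataset"
config <- readRDS(file.path(dataset_dir, "config.rds"))
reference <- load_reference(file.path(dataset_dir, "reference.fasta"))
manifest <- readr::read_csv(file.path(dataset_dir, "manifest.csv"),
                            comment = "#", show_col_types = FALSE)
chroms <- readr::read_csv(file.path(dataset_dir, "chromatograms.csv"),
                          comment = "#", show_col_types = FALSE)

t0 <- Sys.time()
stereo <- dplyr::bind_rows(lapply(split(chroms, chroms$variant_id),
                                  function(cc) {
  res <- analyze_chromatogram(cc[, c("time_min", "signal")],
                              min_total_area = config$chrom$min_total_area)
  tibble::tibble(variant_id = cc$variant_id[1],
                 area_2R3S = res$areas[["2R3S"]],
                 area_2S3R = res$areas[["2S3R"]],
                 area_anti1 = res$areas[["anti1"]],
                 area_anti2 = res$areas[["anti2"]],
                 dr_syn = res$dr[["syn"]], er_2R3S = res$er[["2R3S"]],
                 sufficient_signal = res$sufficient_signal)
}))
message(sprintf("integrated %d chromatograms in %.1f s (%d with insufficient signal)",
                nrow(stereo), as.numeric(Sys.time() - t0, units = "secs"),
                sum(!stereo$sufficient_signal)))
readr::write_csv(stereo, "results/stereo.csv")

idx <- match(stereo$variant_id, manifest$variant_id)
records <- tibble::tibble(
  position = manifest$position[idx], mut_aa = manifest$mut_aa[idx],
  state = ifelse(stereo$sufficient_signal & !is.na(stereo$er_2R3S),
                 "value", "insufficient_signal"),
  value = stereo$er_2R3S)
ls_er <- assemble_landscape(records, "er", manifest, reference, wt_value = 57)
write_landscape_csv(ls_er, "results/landscape_er.csv")
print(ls_er)

inversions <- find_inversions(ls_er, wt_majority = "2R3S")
readr::write_csv(inversions, "results/inversions.csv")
message(sprintf("%d variants invert the enantiopreference toward 2S3R; strongest: %s",
                nrow(inversions),
                paste(head(inversions$mut_aa[order(inversions$value)], 3),
                      collapse = ", ")))
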