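# Orchestration: simulate a full screening dataset to disk and run the
# whole analysis chain over it, with deterministic seeding and provenance
# in every output.

#' Default run configuration
#'
#' Collects every knob of the simulation and analysis chain. Defaults are
#' the screen's working conditions: a 1,040-member collection covering at
#' least 15 of 19 substitutions per position, duplicate variant wells with
#' 4 wild-type and 4 empty-vector controls per plate, the 0.5 mg/ml
#' densitometric detection limit, the 20%-depletion rate window and
#' 5-fold hotspot threshold.
#'
#' @param seed Master seed; all per-stage seeds derive from it.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    collection = list(min_per_position = 15L, total = 1040L),
    truth = list(wt_conc_mg_ml = 2, conc_sdlog = 0.7,
                 rel_meanlog = log(0.7), rel_sdlog = 0.6,
                 zero_fraction = 0.05, stereo_sdlog = 0.8,
                 # the screen's printed single-mutant effects for the
                 # butanal Michael addition, planted as ground truth
                 rel_overrides = c(H6M = 3, A33E = 4, M45I = 2.1,
                                   M45Y = 2.3, M45H = 3.6, M45T = 2,
                                   F50L = 2.5, F50V = 5),
                 # printed e.r. anchors: F50A inverts to 7:93, R39E
                 # sharpens the wild-type preference to 94:6
                 er_overrides = c(F50A = 7, R39E = 94)),
    assay = assay_michael_butanal(),
    plate = list(variants_per_plate = 40L, n_wt = 4L, n_ev = 4L,
                 wt_rate_uM_min = 2.5, ev_rate_uM_min = 0.25,
                 noise_sd = 0.003),
    gel = list(gain = 1000, intercept = 50, noise_rel = 0.01,
               loaded_volume_ul = 1, lod_mg_ml = 0.5),
    rates = list(min_points = 7L, max_fraction_depleted = 0.2),
    chrom = list(total_area = 100, baseline = 2, noise_sd = 0,
                 interval_min = 0.01, duration_min = 16,
                 min_total_area = 1),
    thresholds = list(hotspot_fold = 5, beneficial = 2, detrimental = 0.5)
  ), class = "run_config")
}

config_hash <- function(config) rlang::hash(config)

provenance_line <- function(config) {
  sprintf("# mutscape provenance: seed=%d config=%s", config$seed,
          config_hash(config))
}

write_with_provenance <- function(df, path, config) {
  writeLines(provenance_line(config), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_stage_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

#' Simulate a complete screening dataset to a directory
#'
#' Writes everything the analysis stages consume: reference FASTA,
#' variant manifest, ground-truth table, per-plate progress-curve CSVs,
#' gel band-intensity CSVs and one long chromatogram CSV. All files are
#' UTF-8 CSVs with a provenance comment line (seed, config hash).
#'
#' @param config A [default_config()] list.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
run_simulate <- function(config = default_config(), dir) {
  if (!dir.create(dir, showWarnings = FALSE, recursive = TRUE) &&
      !dir.exists(dir)) {
    stop("cannot create dataset directory ", dir, call. = FALSE)
  }
  reference <- load_reference()
  manifest <- make_collection(reference,
                              min_per_position = config$collection$min_per_position,
                              total = config$collection$total,
                              seed = config$seed)
  tt <- config$truth
  # overrides only apply to variants the drawn collection actually holds
  rel_ov <- tt$rel_overrides[names(tt$rel_overrides) %in%
                               manifest$variant_id]
  stereo_ov <- NULL
  if (!is.null(tt$er_overrides)) {
    keep <- names(tt$er_overrides) %in% manifest$variant_id
    stereo_ov <- lapply(tt$er_overrides[keep], function(p) {
      f <- wt_stereo_fractions()
      syn <- f[["2R3S"]] + f[["2S3R"]]
      c(syn * p / 100, syn * (1 - p / 100), f[["anti1"]], f[["anti2"]])
    })
  }
  truth <- make_truth(manifest, seed = config$seed + 1L,
                      wt_conc_mg_ml = tt$wt_conc_mg_ml,
                      conc_sdlog = tt$conc_sdlog,
                      rel_meanlog = tt$rel_meanlog, rel_sdlog = tt$rel_sdlog,
                      zero_fraction = tt$zero_fraction,
                      stereo_sdlog = tt$stereo_sdlog,
                      rel_overrides = if (length(rel_ov)) rel_ov,
                      stereo_overrides = stereo_ov)
  file.copy(system.file("extdata", "4ot_reference.fasta", package = "mutscape"),
            file.path(dir, "reference.fasta"), overwrite = TRUE)
  write_with_provenance(manifest, file.path(dir, "manifest.csv"), config)
  write_with_provenance(truth, file.path(dir, "truth.csv"), config)

  # gels: up to 22 sample lanes next to the 4 calibration lanes
  gel_cfg <- config$gel
  chunks <- split(seq_len(nrow(manifest)),
                  ceiling(seq_len(nrow(manifest)) / 22L))
  gels <- dplyr::bind_rows(lapply(seq_along(chunks), function(g) {
    rows <- manifest[chunks[[g]], ]
    samples <- tibble::tibble(
      variant_id = rows$variant_id,
      conc_mg_ml = truth$true_conc[match(rows$variant_id, truth$variant_id)])
    simulate_gel(samples, loaded_volume_ul = gel_cfg$loaded_volume_ul,
                 gain = gel_cfg$gain, intercept = gel_cfg$intercept,
                 noise_sd = gel_cfg$noise_rel * gel_cfg$gain,
                 gel_id = sprintf("G%02d", g), seed = config$seed + 100L + g)
  }))
  write_with_provenance(gels, file.path(dir, "gels.csv"), config)

  # plates: duplicate wells per variant plus controls
  pl <- config$plate
  plate_chunks <- split(seq_len(nrow(manifest)),
                        ceiling(seq_len(nrow(manifest)) / pl$variants_per_plate))
  plates <- dplyr::bind_rows(lapply(seq_along(plate_chunks), function(p) {
    simulate_plate(manifest[plate_chunks[[p]], ], truth, config$assay,
                   n_wt = pl$n_wt, n_ev = pl$n_ev,
                   wt_rate_uM_min = pl$wt_rate_uM_min,
                   ev_rate_uM_min = pl$ev_rate_uM_min,
                   wt_conc_mg_ml = tt$wt_conc_mg_ml,
                   noise_sd = pl$noise_sd,
                   plate_id = sprintf("P%02d", p),
                   seed = config$seed + 1000L + p)
  }))
  write_with_provenance(plates, file.path(dir, "plates.csv"), config)

  # chromatograms: duplicates are pooled before HPLC, one trace per variant
  ch <- config$chrom
  fr <- as.matrix(truth[, c("f_2R3S", "f_2S3R", "f_anti1", "f_anti2")])
  chroms <- dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i) {
    # product amount scales with Michaelase activity: inactive variants
    # give too little adduct for an adequate UV signal
    area <- ch$total_area * truth$true_rel_activity[i]
    cc <- simulate_chromatogram(fr[i, ], total_area = area,
                                baseline = ch$baseline,
                                noise_sd = ch$noise_sd,
                                duration_min = ch$duration_min,
                                interval_min = ch$interval_min,
                                seed = config$seed + 10000L + i)
    cc$variant_id <- truth$variant_id[i]
    cc
  }))
  write_with_provenance(chroms, file.path(dir, "chromatograms.csv"), config)
  yaml::write_yaml(list(seed = config$seed, config_hash = config_hash(config)),
                   file.path(dir, "provenance.yaml"))
  invisible(dir)
}

records_from_activity <- function(activity, manifest) {
  var <- activity[activity$role == "variant", ]
  idx <- match(var$variant_id, manifest$variant_id)
  tibble::tibble(position = manifest$position[idx],
                 mut_aa = manifest$mut_aa[idx],
                 state = var$state,
                 value = var$relative)
}

#' Run the full analysis chain over a simulated dataset
#'
#' Reads the raw files written by [run_simulate()] and produces the
#' expression, relative-activity and enantioselectivity landscapes plus
#' hotspot and inversion reports, each written as CSV with a provenance
#' header. When a truth table is present, recovery metrics (measured vs
#' true) are written alongside.
#'
#' @param dir Dataset directory.
#' @param config The [default_config()] used to simulate (analysis knobs
#'   are read from it).
#' @param out_dir Output directory; defaults to `dir`.
#' @return List with the three `landscape` objects, `hotspots`,
#'   `inversions`, `expression`, `activity`, `stereo`, and (if truth was
#'   available) `recovery`.
#' @export
run_pipeline <- function(dir, config = default_config(), out_dir = dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- load_reference(file.path(dir, "reference.fasta"))
  manifest <- read_stage_csv(file.path(dir, "manifest.csv"))
  if (nrow(manifest) == 0L) {
    warning("empty manifest: producing empty landscapes")
  }
  gels <- read_stage_csv(file.path(dir, "gels.csv"))
  plates <- read_stage_csv(file.path(dir, "plates.csv"))

  expression <- quantify_gel(gels,
                             loaded_volume_ul = config$gel$loaded_volume_ul,
                             lod_mg_ml = config$gel$lod_mg_ml)
  write_with_provenance(expression, file.path(out_dir, "expression.csv"),
                        config)

  activity <- dplyr::bind_rows(lapply(split(plates, plates$plate_id),
                                      function(p) {
    analyze_plate(p, config$assay, expression,
                  wt_conc_mg_ml = config$truth$wt_conc_mg_ml,
                  min_points = config$rates$min_points,
                  max_fraction_depleted = config$rates$max_fraction_depleted)
  }))
  write_with_provenance(activity, file.path(out_dir, "activity.csv"), config)

  chrom_path <- file.path(dir, "chromatograms.csv")
  stereo <- NULL
  if (file.exists(chrom_path)) {
    chroms <- read_stage_csv(chrom_path)
    stereo <- dplyr::bind_rows(lapply(split(chroms, chroms$variant_id),
                                      function(cc) {
      res <- analyze_chromatogram(cc[, c("time_min", "signal")],
                                  min_total_area = config$chrom$min_total_area)
      tibble::tibble(variant_id = cc$variant_id[1L],
                     area_2R3S = res$areas[["2R3S"]],
                     area_2S3R = res$areas[["2S3R"]],
                     area_anti1 = res$areas[["anti1"]],
                     area_anti2 = res$areas[["anti2"]],
                     dr_syn = res$dr[["syn"]],
                     er_2R3S = res$er[["2R3S"]],
                     sufficient_signal = res$sufficient_signal)
    }))
    write_with_provenance(stereo, file.path(out_dir, "stereo.csv"), config)
  }

  # landscapes
  expr_records <- {
    idx <- match(expression$variant_id, manifest$variant_id)
    tibble::tibble(position = manifest$position[idx],
                   mut_aa = manifest$mut_aa[idx],
                   state = ifelse(expression$below_lod, "below_lod", "value"),
                   value = expression$conc_mg_ml)
  }
  ls_expr <- assemble_landscape(expr_records, "expression", manifest,
                                reference,
                                wt_value = config$truth$wt_conc_mg_ml)
  ls_act <- assemble_landscape(records_from_activity(activity, manifest),
                               "relative_activity", manifest, reference)
  result <- list(expression_landscape = ls_expr,
                 activity_landscape = ls_act,
                 expression = expression, activity = activity)
  write_landscape_csv(ls_expr, file.path(out_dir, "landscape_expression.csv"))
  write_landscape_csv(ls_act, file.path(out_dir, "landscape_activity.csv"))

  hotspots <- find_hotspots(ls_act,
                            fold_threshold = config$thresholds$hotspot_fold)
  write_with_provenance(hotspots, file.path(out_dir, "hotspots.csv"), config)
  result$hotspots <- hotspots

  if (!is.null(stereo)) {
    st_records <- {
      idx <- match(stereo$variant_id, manifest$variant_id)
      tibble::tibble(position = manifest$position[idx],
                     mut_aa = manifest$mut_aa[idx],
                     state = ifelse(stereo$sufficient_signal &
                                      !is.na(stereo$er_2R3S),
                                    "value", "insufficient_signal"),
                     value = stereo$er_2R3S)
    }
    ls_er <- assemble_landscape(st_records, "er", manifest, reference,
                                wt_value = 57)
    write_landscape_csv(ls_er, file.path(out_dir, "landscape_er.csv"))
    inversions <- find_inversions(ls_er, wt_majority = "2R3S")
    write_with_provenance(inversions, file.path(out_dir, "inversions.csv"),
                          config)
    result$er_landscape <- ls_er
    result$inversions <- inversions
    result$stereo <- stereo
  }

  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path) && nrow(manifest) > 0L) {
    truth <- read_stage_csv(truth_path)
    result$recovery <- recovery_metrics(result, truth)
    write_with_provenance(result$recovery, file.path(out_dir, "recovery.csv"),
                          config)
  }
  result
}

#' Recovery metrics against a truth table
#'
#' Joins pipeline estimates to the generator's ground truth and
#' summarises the agreement: median absolute relative error of expression
#' and of relative activity (over valued cells), and the median absolute
#' e.r. error in percentage points.
#'
#' @param result A [run_pipeline()] result list.
#' @param truth Truth table from [make_truth()].
#' @return One-row tibble of summary metrics.
#' @export
recovery_metrics <- function(result, truth) {
  expr <- result$expression
  i <- match(expr$variant_id, truth$variant_id)
  expr_err <- abs(expr$conc_mg_ml - truth$true_conc[i]) / truth$true_conc[i]
  act <- result$activity[result$activity$role == "variant" &
                           result$activity$state == "value", ]
  j <- match(act$variant_id, truth$variant_id)
  ok <- truth$true_rel_activity[j] > 0
  act_err <- abs(act$relative[ok] - truth$true_rel_activity[j][ok]) /
    truth$true_rel_activity[j][ok]
  er_err <- NA_real_
  if (!is.null(result$stereo)) {
    st <- result$stereo[result$stereo$sufficient_signal &
                          !is.na(result$stereo$er_2R3S), ]
    k <- match(st$variant_id, truth$variant_id)
    true_er <- 100 * truth$f_2R3S[k] / (truth$f_2R3S[k] + truth$f_2S3R[k])
    er_err <- stats::median(abs(st$er_2R3S - true_er))
  }
  tibble::tibble(n_expression = length(expr_err),
                 expr_median_rel_err = stats::median(expr_err),
                 n_activity = sum(ok),
                 activity_median_rel_err = stats::median(act_err),
                 er_median_abs_err_pp = er_err)
}
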