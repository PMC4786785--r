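# Synthetic-data generators: emulate every raw input the analysis stages
# consume (variant manifest, plate-reader progress curves, gel band
# intensities, chiral chromatograms) together with a ground-truth table so
# recovery can be measured.

#' Draw a site-saturation variant collection
#'
#' Samples a collection of single amino-acid substitutions over positions 2
#' to the C-terminus, mimicking a bought site-saturation collection: every
#' position carries at least `min_per_position` of its 19 possible
#' substitutions and the collection has exactly `total` members. Position 1
#' (the catalytic proline) is never mutated.
#'
#' @param reference Reference sequence string (see [load_reference()]).
#' @param min_per_position Minimum substitutions per position (1..19).
#' @param total Total collection size; must lie between
#'   `n_positions * min_per_position` and `n_positions * 19`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Tibble with columns `variant_id` (e.g. `"A33D"`), `position`,
#'   `wt_aa`, `mut_aa`, sorted by position then mutant residue.
#' @export
make_collection <- function(reference, min_per_position = 15L, total = 1040L,
                            seed = 1L) {
  residues <- strsplit(unname(reference), "", fixed = TRUE)[[1L]]
  positions <- seq(2L, length(residues))
  n_pos <- length(positions)
  if (min_per_position < 1L || min_per_position > 19L) {
    stop("min_per_position must be in 1..19", call. = FALSE)
  }
  if (total < n_pos * min_per_position) {
    stop(sprintf("infeasible: total (%d) < %d positions x %d minimum",
                 total, n_pos, min_per_position), call. = FALSE)
  }
  if (total > n_pos * 19L) {
    stop(sprintf("infeasible: total (%d) exceeds the %d possible singles",
                 total, n_pos * 19L), call. = FALSE)
  }
  all_subs <- do.call(rbind, lapply(positions, function(p) {
    muts <- setdiff(aa_alphabet(), residues[p])
    data.frame(position = p, wt_aa = residues[p], mut_aa = muts,
               stringsAsFactors = FALSE)
  }))
  picked <- with_seed(seed, {
    base_idx <- unlist(lapply(split(seq_len(nrow(all_subs)), all_subs$position),
                              function(idx) sample(idx, min_per_position)))
    extra_n <- total - length(base_idx)
    pool <- setdiff(seq_len(nrow(all_subs)), base_idx)
    c(base_idx, if (extra_n > 0L) sample(pool, extra_n))
  })
  out <- all_subs[sort(picked), , drop = FALSE]
  out$variant_id <- paste0(out$wt_aa, out$position, out$mut_aa)
  tibble::as_tibble(out[order(out$position, out$mut_aa),
                        c("variant_id", "position", "wt_aa", "mut_aa")])
}

#' Ground-truth table for a variant collection
#'
#' Assigns every collection member a true soluble-protein concentration in
#' the cell-free extract (CFE), a true specific activity relative to wild
#' type, and true stereoisomer fractions of the Michael adduct. Defaults
#' emulate the screen's working regime: expression lognormal around the
#' wild-type level of 2 mg/ml (a few variants fall under the 0.5 mg/ml
#' densitometric detection limit), relative activity lognormal with a
#' mild detrimental bias plus a small fraction of dead variants, and
#' stereoisomer fractions perturbed on the log scale around the wild-type
#' product distribution (d.r. 91:9 syn:anti, e.r. 57:43 within syn).
#'
#' @param collection Manifest from [make_collection()].
#' @param seed Integer seed.
#' @param wt_conc_mg_ml True wild-type soluble-protein concentration.
#' @param conc_sdlog Lognormal spread of variant expression.
#' @param rel_meanlog,rel_sdlog Lognormal location/spread of relative
#'   activity.
#' @param zero_fraction Fraction of variants with no activity at all.
#' @param wt_fractions Wild-type stereoisomer fractions, in the order
#'   2R3S, 2S3R, anti-1, anti-2; must sum to 1.
#' @param stereo_sdlog Log-scale perturbation of variant fractions.
#' @param rel_overrides Named numeric vector (`variant_id` -> true relative
#'   activity) forcing specific scenario values, e.g. `c(A33D = 3.5)`.
#' @param stereo_overrides Named list (`variant_id` -> length-4 fractions).
#' @return Tibble with columns `variant_id`, `true_conc`,
#'   `true_rel_activity`, `f_2R3S`, `f_2S3R`, `f_anti1`, `f_anti2`.
#' @export
make_truth <- function(collection, seed = 1L,
                       wt_conc_mg_ml = 2,
                       conc_sdlog = 0.7,
                       rel_meanlog = log(0.7), rel_sdlog = 0.6,
                       zero_fraction = 0.05,
                       wt_fractions = wt_stereo_fractions(),
                       stereo_sdlog = 0.8,
                       rel_overrides = NULL,
                       stereo_overrides = NULL) {
  stopifnot(abs(sum(wt_fractions) - 1) < 1e-9, all(wt_fractions >= 0))
  n <- nrow(collection)
  out <- with_seed(seed, {
    conc <- stats::rlnorm(n, meanlog = log(wt_conc_mg_ml), sdlog = conc_sdlog)
    rel <- stats::rlnorm(n, meanlog = rel_meanlog, sdlog = rel_sdlog)
    rel[stats::runif(n) < zero_fraction] <- 0
    lf <- matrix(log(pmax(wt_fractions, 1e-12)), nrow = n, ncol = 4L,
                 byrow = TRUE) +
      matrix(stats::rnorm(4L * n, sd = stereo_sdlog), nrow = n)
    fr <- exp(lf) / rowSums(exp(lf))
    tibble::tibble(variant_id = collection$variant_id,
                   true_conc = conc,
                   true_rel_activity = rel,
                   f_2R3S = fr[, 1L], f_2S3R = fr[, 2L],
                   f_anti1 = fr[, 3L], f_anti2 = fr[, 4L])
  })
  if (!is.null(rel_overrides)) {
    idx <- match(names(rel_overrides), out$variant_id)
    if (anyNA(idx)) stop("rel_overrides name not in collection", call. = FALSE)
    out$true_rel_activity[idx] <- unname(rel_overrides)
  }
  if (!is.null(stereo_overrides)) {
    for (id in names(stereo_overrides)) {
      i <- match(id, out$variant_id)
      if (is.na(i)) stop("stereo_overrides name not in collection", call. = FALSE)
      f <- stereo_overrides[[id]]
      stopifnot(length(f) == 4L, abs(sum(f) - 1) < 1e-9, all(f >= 0))
      out[i, c("f_2R3S", "f_2S3R", "f_anti1", "f_anti2")] <- as.list(f)
    }
  }
  out
}

#' Wild-type stereoisomer fractions of the Michael adduct
#'
#' The wild-type enzyme makes the 2-ethyl gamma-nitroaldehyde with a
#' syn:anti diastereomeric ratio of 91:9 and, within syn, an enantiomeric
#' ratio of 57:43 (2R3S:2S3R); the anti enantiomers are split evenly since
#' their ratio is not resolved.
#'
#' @return Named numeric vector of four fractions summing to 1.
#' @export
wt_stereo_fractions <- function() {
  c(`2R3S` = 0.91 * 0.57, `2S3R` = 0.91 * 0.43,
    anti1 = 0.09 / 2, anti2 = 0.09 / 2)
}

#' Describe a UV kinetic assay
#'
#' Bundles the instrument and reaction parameters needed to simulate and to
#' analyse a depletion progress curve. Extinction coefficient and optical
#' path length are configuration, not measured constants: relative
#' activities are invariant to them because the conversion cancels in the
#' wild-type ratio.
#'
#' @param substrate_id Label of the depleting substrate.
#' @param wavelength_nm Detection wavelength.
#' @param substrate_conc_uM Initial substrate concentration in the well.
#' @param duration_s,interval_s Read length and data interval.
#' @param extinction_mM_cm Molar extinction (mM^-1 cm^-1) at the detection
#'   wavelength; arbitrary default.
#' @param path_cm Optical path through the well; arbitrary default for a
#'   100 ul fill of a microtitre plate.
#' @param cfe_fraction Volume fraction of cell-free extract in the well.
#' @param well_volume_ml Reaction volume.
#' @param buffer_pH Assay pH (annotation only).
#' @return An object of class `assay_spec`.
#' @export
assay_spec <- function(substrate_id, wavelength_nm, substrate_conc_uM,
                       duration_s, interval_s,
                       extinction_mM_cm = 14, path_cm = 0.3,
                       cfe_fraction = 0.4, well_volume_ml = 0.1,
                       buffer_pH = 7.3) {
  stopifnot(duration_s > interval_s, interval_s > 0,
            extinction_mM_cm > 0, path_cm > 0,
            substrate_conc_uM > 0, cfe_fraction > 0, well_volume_ml > 0)
  structure(list(substrate_id = substrate_id,
                 wavelength_nm = wavelength_nm,
                 substrate_conc_uM = substrate_conc_uM,
                 duration_s = duration_s, interval_s = interval_s,
                 extinction_mM_cm = extinction_mM_cm, path_cm = path_cm,
                 cfe_fraction = cfe_fraction,
                 well_volume_ml = well_volume_ml,
                 buffer_pH = buffer_pH),
            class = "assay_spec")
}

#' @rdname assay_spec
#' @details `assay_michael_butanal()` is the butanal + trans-beta-
#'   nitrostyrene screen (650 uM substrate, 320 nm, 80 min at 60 s
#'   intervals, 20% CFE, pH 5.5); `assay_michael_acetaldehyde()` is the
#'   acetaldehyde screen (500 uM, 320 nm, 40 min at 60 s, 40% CFE, pH 7.3);
#'   `assay_tautomerase()` is the phenylenolpyruvate screen (400 uM,
#'   283 nm, 40 s at 0.26 s, 0.2% CFE, pH 7.3).
#' @export
assay_michael_butanal <- function() {
  assay_spec("5a", 320, 650, duration_s = 4800, interval_s = 60,
             cfe_fraction = 0.2, buffer_pH = 5.5)
}

#' @rdname assay_spec
#' @export
assay_michael_acetaldehyde <- function() {
  assay_spec("5a", 320, 500, duration_s = 2400, interval_s = 60,
             cfe_fraction = 0.4, buffer_pH = 7.3)
}

#' @rdname assay_spec
#' @export
assay_tautomerase <- function() {
  assay_spec("8", 283, 400, duration_s = 40, interval_s = 0.26,
             extinction_mM_cm = 6, cfe_fraction = 0.002, buffer_pH = 7.3)
}

#' Simulate one depletion progress curve
#'
#' The default kinetic model is two-phase: absorbance falls linearly at the
#' rate set by `true_rate + background_rate` (converted through extinction
#' and path length) until the substrate is exhausted, then stays at zero.
#' Only the initial linear section is consumed downstream, so this makes
#' the ground-truth slope exact. A first-order mode is available for
#' robustness checks.
#'
#' @param spec An [assay_spec()].
#' @param true_rate_uM_min Enzymatic depletion rate (uM/min), >= 0.
#' @param background_rate_uM_min Host-background depletion rate (uM/min).
#' @param noise_sd Homoscedastic Gaussian noise on absorbance (AU).
#' @param seed Integer seed (`NULL` uses the ambient RNG stream).
#' @param model `"two_phase"` (default) or `"first_order"`.
#' @return Tibble with columns `time_s`, `absorbance`.
#' @export
simulate_trace <- function(spec, true_rate_uM_min, background_rate_uM_min = 0,
                           noise_sd = 0.003, seed = NULL,
                           model = c("two_phase", "first_order")) {
  model <- match.arg(model)
  stopifnot(true_rate_uM_min >= 0, background_rate_uM_min >= 0, noise_sd >= 0)
  times <- seq(0, spec$duration_s, by = spec$interval_s)
  conv <- spec$extinction_mM_cm * spec$path_cm / 1000  # AU per uM
  a0 <- conv * spec$substrate_conc_uM
  total <- true_rate_uM_min + background_rate_uM_min
  ideal <- if (model == "two_phase") {
    pmax(a0 - conv * total * times / 60, 0)
  } else {
    k <- total / spec$substrate_conc_uM / 60  # 1/s, matching initial rate
    a0 * exp(-k * times)
  }
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(times), sd = noise_sd))
  } else {
    0
  }
  tibble::tibble(time_s = times, absorbance = ideal + noise)
}

#' Simulate a screening plate
#'
#' Lays out duplicate wells per variant plus wild-type and empty-vector
#' control wells, and simulates one progress curve per well. Every well
#' carries the host-background depletion rate; enzymatic depletion scales
#' with the variant's true relative activity and its enzyme amount
#' (`true_conc / wt_conc_mg_ml`), so downstream per-mg normalization is
#' genuinely exercised.
#'
#' @param variants Manifest rows for the variants on this plate.
#' @param truth Truth table from [make_truth()].
#' @param spec An [assay_spec()].
#' @param n_wt,n_ev Number of wild-type and empty-vector control wells.
#' @param wt_rate_uM_min True wild-type enzymatic depletion rate.
#' @param ev_rate_uM_min True host-background depletion rate.
#' @param wt_conc_mg_ml Wild-type enzyme concentration in its CFE.
#' @param noise_sd Absorbance noise (AU).
#' @param plate_id Plate label.
#' @param seed Integer seed.
#' @param capacity Number of wells on the plate.
#' @return Long tibble: `plate_id`, `well`, `role`
#'   (`variant`/`wt`/`ev`), `variant_id`, `time_s`, `absorbance`.
#' @export
simulate_plate <- function(variants, truth, spec, n_wt = 4L, n_ev = 4L,
                           wt_rate_uM_min = 2.5, ev_rate_uM_min = 0.25,
                           wt_conc_mg_ml = 2, noise_sd = 0.003,
                           plate_id = "P01", seed = 1L, capacity = 96L) {
  n_wells <- 2L * nrow(variants) + n_wt + n_ev
  if (n_wells > capacity) {
    stop(sprintf("plate overflow: %d wells needed, capacity %d",
                 n_wells, capacity), call. = FALSE)
  }
  if (n_wt < 1L || n_ev < 1L) {
    stop("at least one wild-type and one empty-vector well are required",
         call. = FALSE)
  }
  tr <- truth[match(variants$variant_id, truth$variant_id), ]
  if (anyNA(tr$variant_id)) stop("variant missing from truth table", call. = FALSE)
  roles <- c(rep("variant", 2L * nrow(variants)), rep("wt", n_wt),
             rep("ev", n_ev))
  ids <- c(rep(variants$variant_id, each = 2L), rep(NA_character_, n_wt + n_ev))
  rates <- c(rep(wt_rate_uM_min * tr$true_rel_activity *
                   tr$true_conc / wt_conc_mg_ml, each = 2L),
             rep(wt_rate_uM_min, n_wt), rep(0, n_ev))
  wells <- sprintf("%s%02d", rep(LETTERS[1:8], length.out = n_wells),
                   ((seq_len(n_wells) - 1L) %/% 8L) + 1L)
  traces <- with_seed(seed, {
    lapply(seq_len(n_wells), function(i) {
      simulate_trace(spec, true_rate_uM_min = rates[i],
                     background_rate_uM_min = ev_rate_uM_min,
                     noise_sd = noise_sd, seed = NULL)
    })
  })
  n_t <- nrow(traces[[1L]])
  tibble::tibble(
    plate_id = plate_id,
    well = rep(wells, each = n_t),
    role = rep(roles, each = n_t),
    variant_id = rep(ids, each = n_t),
    time_s = unlist(lapply(traces, `[[`, "time_s")),
    absorbance = unlist(lapply(traces, `[[`, "absorbance"))
  )
}

#' Simulate a densitometry gel
#'
#' One gel carries four calibration lanes loaded with 0.5, 1, 2.5 and 5 ug
#' of purified wild-type enzyme plus up to 22 sample lanes (26-well gel).
#' Band intensity is linear in loaded protein with a background intercept
#' and Gaussian noise. Sample lanes report the *unknown* load as `NA`: the
#' analyst only sees intensity.
#'
#' @param samples Tibble with `variant_id` and `conc_mg_ml` (true CFE
#'   concentration) for the sample lanes.
#' @param loaded_volume_ul CFE-equivalent volume loaded per sample lane;
#'   the default 1 ul mirrors 2 ul CFE diluted 1:10 with 10 of 20 ul
#'   loaded.
#' @param cal_loads_ug Calibration loads (ug).
#' @param gain Intensity per ug of protein.
#' @param intercept Background intensity of an empty lane.
#' @param noise_sd Intensity noise (same units as intensity).
#' @param gel_id Gel label.
#' @param seed Integer seed.
#' @return Tibble: `gel_id`, `lane`, `role` (`calibration`/`sample`),
#'   `variant_id`, `load_ug` (NA for samples), `intensity`.
#' @export
simulate_gel <- function(samples, loaded_volume_ul = 1,
                         cal_loads_ug = c(0.5, 1, 2.5, 5),
                         gain = 1000, intercept = 50, noise_sd = 0,
                         gel_id = "G01", seed = 1L) {
  stopifnot(all(cal_loads_ug >= 0), noise_sd >= 0, loaded_volume_ul > 0)
  if (nrow(samples) > 26L - length(cal_loads_ug)) {
    stop("too many sample lanes for a 26-well gel", call. = FALSE)
  }
  loads <- c(cal_loads_ug, samples$conc_mg_ml * loaded_volume_ul)
  n <- length(loads)
  noise <- if (noise_sd > 0) with_seed(seed, stats::rnorm(n, sd = noise_sd)) else 0
  tibble::tibble(
    gel_id = gel_id,
    lane = seq_len(n),
    role = c(rep("calibration", length(cal_loads_ug)),
             rep("sample", nrow(samples))),
    variant_id = c(rep(NA_character_, length(cal_loads_ug)),
                   samples$variant_id),
    load_ug = c(cal_loads_ug, rep(NA_real_, nrow(samples))),
    intensity = gain * loads + intercept + noise
  )
}

#' Default retention-time layout of the four stereoisomer peaks
#'
#' Retention times (min) used by the chromatogram generator and, as
#' windows, by the assignment step. The real column's retention times are
#' instrument-specific configuration; these defaults close the simulation
#' loop. Syn enantiomers elute first (2R3S, then 2S3R), followed by the two
#' anti enantiomers labelled by elution order.
#'
#' @return Named numeric vector of apex retention times.
#' @export
default_rt <- function() {
  c(`2R3S` = 8, `2S3R` = 10, anti1 = 12.5, anti2 = 14)
}

#' Simulate a chiral-HPLC chromatogram
#'
#' Sum of four Gaussian peaks whose areas follow the requested
#' stereoisomer fractions, on a flat baseline, with optional Gaussian
#' noise.
#'
#' @param fractions Length-4 fractions (2R3S, 2S3R, anti-1, anti-2)
#'   summing to 1.
#' @param rt_min Apex retention times (min), all distinct.
#' @param width_min Gaussian sigma per peak (min).
#' @param total_area Total peak area (detector units x min).
#' @param baseline Flat baseline level.
#' @param noise_sd Signal noise.
#' @param duration_min,interval_min Trace length and sampling interval.
#' @param seed Integer seed.
#' @return Tibble with columns `time_min`, `signal`.
#' @export
simulate_chromatogram <- function(fractions, rt_min = default_rt(),
                                  width_min = rep(0.15, 4L),
                                  total_area = 100, baseline = 2,
                                  noise_sd = 0, duration_min = 16,
                                  interval_min = 0.005, seed = NULL) {
  stopifnot(length(fractions) == 4L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-6,
            length(rt_min) == 4L, anyDuplicated(rt_min) == 0L,
            length(width_min) == 4L, all(width_min > 0))
  t <- seq(0, duration_min, by = interval_min)
  signal <- rep(baseline, length(t))
  areas <- total_area * fractions
  for (i in seq_len(4L)) {
    signal <- signal + areas[i] / (width_min[i] * sqrt(2 * pi)) *
      exp(-0.5 * ((t - rt_min[i]) / width_min[i])^2)
  }
  if (noise_sd > 0) {
    signal <- signal + with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
  }
  tibble::tibble(time_min = t, signal = signal)
}
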