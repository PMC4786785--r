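# Initial-rate extraction from UV progress curves, empty-vector background
# subtraction, specific activity and per-plate wild-type normalization.

#' Initial rate from a depletion progress curve
#'
#' Finds the linear section of a progress curve by sliding a
#' fixed-length window over the early region of the trace -- the span in
#' which at most `max_fraction_depleted` of the initial signal has been
#' lost -- and keeping the window with the highest R^2 (earliest window on
#' ties). The window length is half the admissible span, floored at
#' `min_points`, so slow traces are fitted over many points while fast
#' traces stay inside their short linear phase. The fitted slope (AU/min)
#' is converted to uM/min through the assay's extinction coefficient and
#' path length; rising slopes clip to rate zero.
#'
#' @param trace Tibble with `time_s` and `absorbance`.
#' @param spec The [assay_spec()] the trace was recorded under.
#' @param min_points Minimum points per fit window.
#' @param max_fraction_depleted Depletion cap defining the admissible
#'   early region (default 20% of the initial signal).
#' @return List: `rate_uM_min`, `slope_au_min`, `r_squared`,
#'   `window` (start/end indices), `n_points`.
#' @export
initial_rate <- function(trace, spec, min_points = 7L,
                         max_fraction_depleted = 0.2) {
  y <- trace$absorbance
  t_min <- trace$time_s / 60
  n <- length(y)
  if (n < min_points) {
    stop("trace has fewer than min_points samples", call. = FALSE)
  }
  a0 <- y[1L]
  floor_au <- a0 - max_fraction_depleted * abs(a0)
  crossed <- which(y < floor_au)
  last <- if (length(crossed) == 0L) n else max(crossed[1L] - 1L, 2L)
  last <- max(last, min(min_points, n))
  w <- max(min_points, floor(last / 2))
  w <- min(w, last)
  starts <- seq_len(last - w + 1L)
  best <- list(r2 = -Inf, slope = 0, start = 1L)
  for (s in starts) {
    idx <- s:(s + w - 1L)
    fit <- ols_line(t_min[idx], y[idx])
    if (fit$r_squared > best$r2 + 1e-12) {
      best <- list(r2 = fit$r_squared, slope = fit$slope, start = s)
    }
  }
  conv <- spec$extinction_mM_cm * spec$path_cm / 1000  # AU per uM
  rate <- max(-best$slope, 0) / conv
  list(rate_uM_min = rate, slope_au_min = best$slope,
       r_squared = max(best$r2, 0),
       window = c(start = best$start, end = best$start + w - 1L),
       n_points = w)
}

#' Pointwise-average duplicate variant traces
#'
#' Variant wells are screened in duplicate; the duplicates are combined
#' into one average progress curve before rate fitting. Control wells
#' (wild type, empty vector) are left as individual wells because their
#' rates are averaged downstream, not their traces.
#'
#' @param plate Long plate table from [simulate_plate()] (or same dialect).
#' @return Plate table in the same dialect with one merged trace per
#'   variant (well id `"avg"`), controls untouched.
#' @export
average_duplicates <- function(plate) {
  var <- plate[plate$role == "variant", ]
  ctl <- plate[plate$role != "variant", ]
  if (nrow(var) > 0L) {
    var <- dplyr::summarise(
      dplyr::group_by(var, .data$plate_id, .data$role, .data$variant_id,
                      .data$time_s),
      absorbance = mean(.data$absorbance), .groups = "drop")
    var$well <- "avg"
    var <- var[, c("plate_id", "well", "role", "variant_id", "time_s",
                   "absorbance")]
  }
  dplyr::bind_rows(var, ctl[, c("plate_id", "well", "role", "variant_id",
                                "time_s", "absorbance")])
}

#' Plate background depletion rate
#'
#' Mean initial rate over the empty-vector control wells of one plate:
#' the non-enzymatic (host) substrate depletion that is subtracted from
#' every other well on the same plate.
#'
#' @inheritParams initial_rate
#' @param plate Long plate table containing `role == "ev"` wells.
#' @return Background rate in uM/min.
#' @export
background_rate <- function(plate, spec, min_points = 7L,
                            max_fraction_depleted = 0.2) {
  ev <- plate[plate$role == "ev", ]
  if (nrow(ev) == 0L) {
    stop("no empty-vector wells on plate", call. = FALSE)
  }
  rates <- vapply(split(ev, ev$well), function(tr) {
    initial_rate(tr, spec, min_points, max_fraction_depleted)$rate_uM_min
  }, numeric(1L))
  mean(rates)
}

#' Specific activity of a well
#'
#' Subtracts the plate background from the observed depletion rate,
#' converts to enzyme units (U = umol/min) through the reaction volume,
#' and divides by the enzyme mass in the well (CFE concentration x CFE
#' volume). States: `below_lod` when the expression measurement was under
#' the detection limit (regardless of rate), `zero_activity` when the
#' background-corrected rate is <= 0, otherwise `value`.
#'
#' @param rate_uM_min Observed initial rate(s).
#' @param background_uM_min Plate background rate.
#' @param conc_mg_ml Enzyme concentration in the CFE (mg/ml).
#' @param below_lod Logical flag(s) from the expression stage.
#' @param spec The [assay_spec()].
#' @return Tibble: `rate_uM_min`, `U`, `specific_activity`, `state`.
#' @export
specific_activity <- function(rate_uM_min, background_uM_min, conc_mg_ml,
                              below_lod, spec) {
  corrected <- rate_uM_min - background_uM_min
  u <- pmax(corrected, 0) * spec$well_volume_ml / 1000  # umol/min
  mass_mg <- conc_mg_ml * spec$cfe_fraction * spec$well_volume_ml
  sa <- ifelse(mass_mg > 0, u / mass_mg, NA_real_)
  state <- ifelse(below_lod, "below_lod",
                  ifelse(corrected <= 0, "zero_activity", "value"))
  sa[state != "value"] <- ifelse(state[state != "value"] == "zero_activity",
                                 0, NA_real_)
  tibble::tibble(rate_uM_min = rate_uM_min, U = u,
                 specific_activity = sa, state = state)
}

#' Per-plate wild-type normalization
#'
#' Divides each valued specific activity by the arithmetic mean of the
#' wild-type specific activities measured on the same plate (the screen's
#' reference convention; a median switch is provided). Wild-type and
#' empty-vector controls are never used across plates.
#'
#' @param records Activity records of a single plate: tibble with `role`,
#'   `specific_activity`, `state`.
#' @param method `"mean"` (default) or `"median"` wild-type reference.
#' @return `records` with columns `relative` and `wt_reference` added.
#'   When a plate has no valued wild-type record, every record is flagged
#'   un-normalizable (`relative` NA) with a warning.
#' @export
relative_activity <- function(records, method = c("mean", "median")) {
  method <- match.arg(method)
  wt <- records$specific_activity[records$role == "wt" &
                                    records$state == "value"]
  if (length(wt) == 0L) {
    warning("no valued wild-type record on plate; records are un-normalizable")
    records$relative <- NA_real_
    records$wt_reference <- NA_real_
    return(records)
  }
  ref <- if (method == "mean") mean(wt) else stats::median(wt)
  records$relative <- ifelse(records$state == "value" | records$state == "zero_activity",
                             records$specific_activity / ref, NA_real_)
  records$wt_reference <- ref
  records
}

#' Full kinetic analysis of one screening plate
#'
#' Averages duplicate variant traces, fits initial rates for variant and
#' control wells, subtracts the empty-vector background, converts to
#' specific activities using the expression measurements, and normalizes
#' against the plate's wild-type wells.
#'
#' @param plate Long plate table.
#' @param spec The [assay_spec()].
#' @param expression Tibble with `variant_id`, `conc_mg_ml`, `below_lod`
#'   (from [quantify_gel()] or the truth table in simulations).
#' @param wt_conc_mg_ml Known concentration of the wild-type control
#'   stock (an input constant, measured off-plate).
#' @inheritParams initial_rate
#' @param method Wild-type reference statistic, see [relative_activity()].
#' @return Tibble with one row per variant plus one per control well:
#'   `plate_id`, `variant_id`, `role`, `rate_uM_min`, `U`,
#'   `specific_activity`, `state`, `relative`, `wt_reference`,
#'   `fit_r2`, `window_start`, `window_end`.
#' @export
analyze_plate <- function(plate, spec, expression, wt_conc_mg_ml = 2,
                          min_points = 7L, max_fraction_depleted = 0.2,
                          method = "mean") {
  merged <- average_duplicates(plate)
  bg <- background_rate(merged, spec, min_points, max_fraction_depleted)
  keep <- merged[merged$role != "ev", ]
  keys <- unique(keep[, c("plate_id", "well", "role", "variant_id")])
  fits <- lapply(seq_len(nrow(keys)), function(i) {
    tr <- if (keys$role[i] == "variant") {
      keep[keep$role == "variant" & keep$variant_id == keys$variant_id[i], ]
    } else {
      keep[keep$role == keys$role[i] & keep$well == keys$well[i], ]
    }
    initial_rate(tr, spec, min_points, max_fraction_depleted)
  })
  conc <- numeric(nrow(keys))
  lod <- logical(nrow(keys))
  is_var <- keys$role == "variant"
  idx <- match(keys$variant_id[is_var], expression$variant_id)
  if (anyNA(idx)) {
    stop("plate contains variants without expression records", call. = FALSE)
  }
  conc[is_var] <- expression$conc_mg_ml[idx]
  lod[is_var] <- expression$below_lod[idx]
  conc[!is_var] <- wt_conc_mg_ml
  lod[!is_var] <- FALSE
  sa <- specific_activity(vapply(fits, `[[`, numeric(1L), "rate_uM_min"),
                          bg, conc, lod, spec)
  rec <- tibble::tibble(
    plate_id = keys$plate_id, variant_id = keys$variant_id,
    role = keys$role,
    rate_uM_min = sa$rate_uM_min, background_uM_min = bg,
    U = sa$U, specific_activity = sa$specific_activity, state = sa$state,
    fit_r2 = vapply(fits, `[[`, numeric(1L), "r_squared"),
    window_start = vapply(fits, function(f) unname(f$window["start"]), numeric(1L)),
    window_end = vapply(fits, function(f) unname(f$window["end"]), numeric(1L)))
  relative_activity(rec, method = method)
}
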