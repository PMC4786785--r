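# Chiral-HPLC analysis: peak detection and trapezoidal integration,
# stereoisomer assignment by retention-time window, and d.r./e.r.

#' Detect and integrate chromatogram peaks
#'
#' Subtracts a flat baseline (by default the 5th percentile of the
#' signal), finds local maxima rising above `min_prominence` of the
#' tallest baseline-corrected signal, and integrates each peak by the
#' trapezoidal rule between its boundaries. A boundary is reached where
#' the signal either falls to `boundary_fraction` of the apex height or
#' turns upward again (a valley shared with a neighbouring peak).
#'
#' @param chrom Tibble with `time_min` and `signal`, times strictly
#'   increasing.
#' @param baseline_method `"quantile"` (flat baseline at
#'   `baseline_quantile`), `"none"`, or a numeric baseline level.
#' @param baseline_quantile Quantile used when `baseline_method =
#'   "quantile"`.
#' @param min_prominence Detection threshold as a fraction of the maximum
#'   baseline-corrected signal.
#' @param boundary_fraction Integration cut-off as a fraction of apex
#'   height.
#' @return Tibble of peaks: `rt_min`, `height`, `area`, `t_start`,
#'   `t_end`; empty (zero rows) for a flat trace.
#' @export
detect_and_integrate <- function(chrom, baseline_method = "quantile",
                                 baseline_quantile = 0.05,
                                 min_prominence = 0.02,
                                 boundary_fraction = 0.001) {
  t <- chrom$time_min
  y <- chrom$signal
  if (length(t) < 3L) stop("chromatogram too short", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  base <- if (is.numeric(baseline_method)) {
    baseline_method
  } else if (identical(baseline_method, "none")) {
    0
  } else {
    stats::quantile(y, baseline_quantile, names = FALSE)
  }
  s <- y - base
  n <- length(s)
  top <- max(s)
  empty <- tibble::tibble(rt_min = numeric(), height = numeric(),
                          area = numeric(), t_start = numeric(),
                          t_end = numeric())
  if (top <= 0) return(empty)
  thr <- min_prominence * top
  apex <- which(s[2:(n - 1L)] > s[1:(n - 2L)] &
                  s[2:(n - 1L)] >= s[3:n] &
                  s[2:(n - 1L)] > thr) + 1L
  if (length(apex) == 0L) return(empty)
  rows <- lapply(apex, function(i) {
    cut <- boundary_fraction * s[i]
    j <- i
    while (j > 1L && s[j - 1L] <= s[j] && s[j - 1L] > cut) j <- j - 1L
    k <- i
    while (k < n && s[k + 1L] <= s[k] && s[k + 1L] > cut) k <- k + 1L
    tibble::tibble(rt_min = t[i], height = s[i],
                   area = pracma::trapz(t[j:k], s[j:k]),
                   t_start = t[j], t_end = t[k])
  })
  dplyr::bind_rows(rows)
}

#' Default stereoisomer retention-time windows
#'
#' Disjoint windows around the generator's default retention times (see
#' [default_rt()]); real instrument dialects override these in
#' configuration.
#'
#' @return Named list label -> c(min, max) in minutes.
#' @export
default_rt_windows <- function() {
  list(`2R3S` = c(7, 9), `2S3R` = c(9.2, 11),
       anti1 = c(11.8, 13.2), anti2 = c(13.4, 14.6))
}

#' Assign integrated peaks to stereoisomers
#'
#' Each peak is assigned to the retention-time window containing its apex;
#' peaks falling outside every window are reported unassigned. The labels
#' follow the screen's convention: the syn enantiomers carry absolute
#' configurations (2R3S, 2S3R, assigned via reference standards) while the
#' anti enantiomers are labelled by elution order only.
#'
#' @param peaks Peak table from [detect_and_integrate()].
#' @param windows Named list label -> c(min, max); windows must be
#'   disjoint.
#' @return List with `areas` (named numeric over all window labels, zero
#'   where no peak landed) and `unassigned` (peak rows outside every
#'   window).
#' @export
assign_stereoisomers <- function(peaks, windows = default_rt_windows()) {
  bounds <- do.call(rbind, windows)
  ord <- order(bounds[, 1L])
  if (any(bounds[ord, 1L][-1L] < bounds[ord, 2L][-length(ord)])) {
    stop("retention-time windows must be disjoint", call. = FALSE)
  }
  areas <- stats::setNames(numeric(length(windows)), names(windows))
  hit <- rep(NA_character_, nrow(peaks))
  for (lab in names(windows)) {
    w <- windows[[lab]]
    inside <- peaks$rt_min >= w[1L] & peaks$rt_min <= w[2L]
    areas[lab] <- areas[lab] + sum(peaks$area[inside])
    hit[inside] <- lab
  }
  list(areas = areas, unassigned = peaks[is.na(hit), , drop = FALSE])
}

#' Diastereomeric and enantiomeric ratios from labelled areas
#'
#' d.r. is the syn:anti split of the total area; e.r. is the 2R3S:2S3R
#' split within syn. Both are percentage pairs summing to 100, stored at
#' full precision (printing rounds to integers, table style). The e.r. is
#' undefined when the syn area is zero, and the whole result is flagged
#' insufficient when total area falls under `min_total_area` -- too little
#' product gives no adequate UV signal.
#'
#' @param areas Named numeric with entries `2R3S`, `2S3R`, `anti1`,
#'   `anti2` (all >= 0).
#' @param min_total_area Signal-sufficiency threshold on the total area.
#' @return Object of class `stereo_result`: `areas`, `dr` (syn, anti),
#'   `er` (2R3S, 2S3R), `ee`, `major` (majority syn enantiomer or NA),
#'   `sufficient_signal`.
#' @export
compute_dr_er <- function(areas, min_total_area = 1) {
  lbl <- c("2R3S", "2S3R", "anti1", "anti2")
  if (!all(lbl %in% names(areas))) {
    stop("areas must be named 2R3S, 2S3R, anti1, anti2", call. = FALSE)
  }
  a <- areas[lbl]
  if (any(a < 0)) stop("areas must be nonnegative", call. = FALSE)
  syn <- a[["2R3S"]] + a[["2S3R"]]
  anti <- a[["anti1"]] + a[["anti2"]]
  total <- syn + anti
  dr <- if (total > 0) 100 * c(syn = syn, anti = anti) / total else
    c(syn = NA_real_, anti = NA_real_)
  er <- if (syn > 0) 100 * c(`2R3S` = a[["2R3S"]], `2S3R` = a[["2S3R"]]) / syn else
    c(`2R3S` = NA_real_, `2S3R` = NA_real_)
  major <- if (!is.na(er[1L]) && er[1L] != 50) {
    if (er[1L] > 50) "2R3S" else "2S3R"
  } else {
    NA_character_
  }
  structure(list(areas = a, dr = dr, er = er,
                 ee = if (all(!is.na(er))) abs(er[[1L]] - er[[2L]]) else NA_real_,
                 major = major,
                 sufficient_signal = total >= min_total_area),
            class = "stereo_result")
}

#' @export
print.stereo_result <- function(x, ...) {
  fmt <- function(p) if (anyNA(p)) "undefined" else
    sprintf("%d:%d", round(p[[1L]]), round(p[[2L]]))
  cat(sprintf("d.r. (syn:anti) %s, e.r. (2R3S:2S3R) %s%s\n",
              fmt(x$dr), fmt(x$er),
              if (x$sufficient_signal) "" else " [insufficient signal]"))
  invisible(x)
}

#' Convert an enantiomeric ratio to enantiomeric excess and back
#'
#' @param er Percentage pair summing to 100.
#' @return `er_to_ee()`: the excess |a - b| in percent.
#' @export
er_to_ee <- function(er) {
  stopifnot(length(er) == 2L, abs(sum(er) - 100) < 1e-6)
  abs(er[[1L]] - er[[2L]])
}

#' @rdname er_to_ee
#' @param ee Enantiomeric excess in percent (0..100).
#' @param major Name of the major component.
#' @param minor Name of the minor component.
#' @return `ee_to_er()`: named percentage pair with the major component
#'   first.
#' @export
ee_to_er <- function(ee, major = "major", minor = "minor") {
  stopifnot(ee >= 0, ee <= 100)
  stats::setNames(c((100 + ee) / 2, (100 - ee) / 2), c(major, minor))
}

#' One-call chromatogram analysis
#'
#' Integrates, assigns and computes d.r./e.r. for a single chromatogram.
#'
#' @inheritParams detect_and_integrate
#' @inheritParams assign_stereoisomers
#' @inheritParams compute_dr_er
#' @return A `stereo_result` (see [compute_dr_er()]); unassigned peaks are
#'   attached as attribute `"unassigned"`.
#' @export
analyze_chromatogram <- function(chrom, windows = default_rt_windows(),
                                 min_total_area = 1,
                                 baseline_method = "quantile",
                                 min_prominence = 0.02) {
  peaks <- detect_and_integrate(chrom, baseline_method = baseline_method,
                                min_prominence = min_prominence)
  asg <- assign_stereoisomers(peaks, windows)
  res <- compute_dr_er(asg$areas, min_total_area = min_total_area)
  attr(res, "unassigned") <- asg$unassigned
  res
}
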