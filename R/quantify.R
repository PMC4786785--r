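# Densitometric quantification: per-gel calibration curves and CFE
# concentration assignment with limit-of-detection semantics.

#' Fit a densitometric calibration curve
#'
#' Ordinary least squares of band intensity on loaded protein for the
#' calibration lanes of one gel (standard loads 0.5, 1, 2.5 and 5 ug). The
#' intercept is free: background staining gives an empty lane a nonzero
#' blank intensity.
#'
#' @param load_ug Loaded protein per calibration lane (>= 3 distinct
#'   values).
#' @param intensity Measured band intensities.
#' @param gel_id Gel label; concentrations may only ever be computed from
#'   the curve of the same gel.
#' @return Object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `gel_id`, `n`.
#' @export
fit_calibration <- function(load_ug, intensity, gel_id = "gel") {
  if (length(load_ug) != length(intensity)) {
    stop("load and intensity lengths differ", call. = FALSE)
  }
  if (length(unique(load_ug)) < 3L) {
    stop("calibration needs at least 3 distinct loads", call. = FALSE)
  }
  fit <- ols_line(load_ug, intensity)
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, gel_id = gel_id,
                 n = length(load_ug)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve [%s]: intensity = %.4g x load + %.4g (R2 = %.4f, n = %d)\n",
              x$gel_id, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Back-calculate a CFE concentration from a band intensity
#'
#' Inverts the calibration line and rescales by the CFE-equivalent loaded
#' volume and dilution to mg of soluble protein per ml of extract.
#' Negative inversions clip to zero (flagged); concentrations under the
#' detection limit are flagged `below_lod`.
#'
#' @param intensity Band intensity (vectorised).
#' @param curve A [fit_calibration()] result with positive slope.
#' @param loaded_volume_ul CFE-equivalent volume in the lane (ul).
#' @param dilution Fold-dilution of the CFE before loading.
#' @param lod_mg_ml Detection limit; the screen's densitometry resolves
#'   0.5 mg/ml.
#' @return Tibble: `conc_mg_ml`, `below_lod`, `clipped`.
#' @export
quantify_lane <- function(intensity, curve, loaded_volume_ul = 1,
                          dilution = 1, lod_mg_ml = 0.5) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("calibration curve has non-positive slope; gel is invalid",
         call. = FALSE)
  }
  load_ug <- (intensity - curve$intercept) / curve$slope
  conc <- load_ug / loaded_volume_ul * dilution  # ug/ul == mg/ml
  clipped <- conc < 0
  conc[clipped] <- 0
  tibble::tibble(conc_mg_ml = conc,
                 below_lod = conc < lod_mg_ml,
                 clipped = clipped)
}

#' Quantify every sample lane of one or more gels
#'
#' Fits the calibration curve of each gel from its own calibration lanes
#' and applies it exclusively to the sample lanes of that same gel.
#'
#' @param gel Gel table in the generator dialect (`gel_id`, `lane`,
#'   `role`, `variant_id`, `load_ug`, `intensity`); several gels may be
#'   stacked.
#' @inheritParams quantify_lane
#' @return Tibble: `variant_id`, `gel_id`, `conc_mg_ml`, `below_lod`,
#'   `clipped`, `r_squared`.
#' @export
quantify_gel <- function(gel, loaded_volume_ul = 1, dilution = 1,
                         lod_mg_ml = 0.5) {
  pieces <- lapply(split(gel, gel$gel_id), function(g) {
    cal <- g[g$role == "calibration", ]
    smp <- g[g$role == "sample", ]
    if (nrow(cal) == 0L) {
      stop("gel ", g$gel_id[1L], " has no calibration lanes", call. = FALSE)
    }
    curve <- fit_calibration(cal$load_ug, cal$intensity,
                             gel_id = g$gel_id[1L])
    q <- quantify_lane(smp$intensity, curve,
                       loaded_volume_ul = loaded_volume_ul,
                       dilution = dilution, lod_mg_ml = lod_mg_ml)
    tibble::tibble(variant_id = smp$variant_id, gel_id = g$gel_id[1L],
                   conc_mg_ml = q$conc_mg_ml, below_lod = q$below_lod,
                   clipped = q$clipped, r_squared = curve$r_squared)
  })
  dplyr::bind_rows(pieces)
}

#' Average effect of each amino-acid substitution
#'
#' Arithmetic mean of an expression landscape over all positions, per
#' substituted amino acid. Wild-type and absent cells are excluded;
#' below-detection cells enter as zero, mirroring their rendering as a
#' floor category in the landscape figure.
#'
#' @param ls A `landscape` object (see [assemble_landscape()]).
#' @return Tibble: `mut_aa`, `mean_value`, `n`.
#' @export
substitution_averages <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  long <- landscape_long(ls)
  keep <- long$state %in% c("value", "below_lod")
  dat <- long[keep, ]
  dat$value[dat$state == "below_lod"] <- 0
  out <- dplyr::summarise(dplyr::group_by(dat, .data$mut_aa),
                          mean_value = mean(.data$value),
                          n = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$mut_aa)
}
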