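# Mutability-landscape assembly: 20 amino acids x positions 2..C-terminus,
# with explicit cell states, hotspot/inversion detection and CSV round
# trips.

LANDSCAPE_STATES <- c("wild_type", "absent", "below_lod", "zero_activity",
                      "insufficient_signal", "value")

#' Assemble a mutability landscape
#'
#' Builds the 20 x (n-1) matrix of one measured property over every
#' substitution at positions 2..n. The collection manifest defines which
#' cells are addressable; manifest cells without a measurement stay
#' `absent`. Each wild-type residue occupies exactly one `wild_type` cell
#' per position; for the relative-activity metric those cells carry 1 by
#' construction.
#'
#' @param records Tibble with `position`, `mut_aa`, `state` and `value`
#'   (value may be NA for non-`value` states). One record per cell.
#' @param metric `"expression"`, `"relative_activity"` or `"er"`.
#' @param manifest Collection manifest (see [make_collection()]).
#' @param reference Reference sequence string.
#' @param aa_order Row order of the matrix (default alphabetical).
#' @param wt_value Optional numeric carried by wild-type cells (e.g. the
#'   wild-type e.r. or expression level); ignored for
#'   `relative_activity`, whose wild-type cells are 1.
#' @return Object of class `landscape` with fields `metric`, `aa_order`,
#'   `positions`, `reference`, `values` (numeric matrix), `states`
#'   (character matrix).
#' @export
assemble_landscape <- function(records, metric, manifest, reference,
                               aa_order = aa_alphabet(), wt_value = NULL) {
  metric <- match.arg(metric, c("expression", "relative_activity", "er"))
  residues <- strsplit(unname(reference), "", fixed = TRUE)[[1L]]
  positions <- seq(2L, length(residues))
  stopifnot(setequal(aa_order, aa_alphabet()))
  values <- matrix(NA_real_, nrow = 20L, ncol = length(positions),
                   dimnames = list(aa_order, positions))
  states <- matrix("absent", nrow = 20L, ncol = length(positions),
                   dimnames = list(aa_order, positions))
  for (j in seq_along(positions)) {
    states[residues[positions[j]], j] <- "wild_type"
    values[residues[positions[j]], j] <-
      if (metric == "relative_activity") 1 else wt_value %||% NA_real_
  }
  if (nrow(records) > 0L) {
    key <- paste0(records$position, records$mut_aa)
    if (anyDuplicated(key)) {
      stop("duplicate records for a landscape cell", call. = FALSE)
    }
    man_key <- paste0(manifest$position, manifest$mut_aa)
    if (!all(key %in% man_key)) {
      stop("record for a variant not in the collection manifest",
           call. = FALSE)
    }
    if (!all(records$state %in% setdiff(LANDSCAPE_STATES, c("wild_type", "absent")))) {
      stop("invalid record state", call. = FALSE)
    }
    jj <- match(as.character(records$position), colnames(states))
    ii <- match(records$mut_aa, rownames(states))
    for (r in seq_len(nrow(records))) {
      states[ii[r], jj[r]] <- records$state[r]
      values[ii[r], jj[r]] <-
        if (records$state[r] == "value") records$value[r] else
          if (records$state[r] == "zero_activity") 0 else NA_real_
    }
  }
  structure(list(metric = metric, aa_order = aa_order,
                 positions = positions, reference = unname(reference),
                 values = values, states = states),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  tab <- table(factor(x$states, levels = LANDSCAPE_STATES))
  cat(sprintf("Mutability landscape [%s]: %d aa x %d positions\n",
              x$metric, nrow(x$values), ncol(x$values)))
  cat("  states:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Long-form view of a landscape
#'
#' @param ls A `landscape`.
#' @return Tibble: `position`, `wt_aa`, `mut_aa`, `state`, `value`.
#' @export
landscape_long <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  residues <- strsplit(ls$reference, "", fixed = TRUE)[[1L]]
  tibble::tibble(
    position = rep(ls$positions, each = nrow(ls$values)),
    wt_aa = rep(residues[ls$positions], each = nrow(ls$values)),
    mut_aa = rep(rownames(ls$values), times = ncol(ls$values)),
    state = as.vector(ls$states),
    value = as.vector(ls$values))
}

#' Write / read a landscape as CSV
#'
#' The long-form CSV is the canonical artifact; a write-read round trip
#' reproduces the matrix bit-exactly. The metric is stored as a column so
#' the file is self-describing.
#'
#' @param ls A `landscape`.
#' @param path Output path.
#' @export
write_landscape_csv <- function(ls, path) {
  long <- landscape_long(ls)
  long$metric <- ls$metric
  # serialize values at 17 significant digits so the round trip is bit-exact
  long$value <- ifelse(is.na(long$value), NA_character_,
                       sprintf("%.17g", long$value))
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @param aa_order Row order for the reconstructed matrix.
#' @return `read_landscape_csv()`: the reconstructed `landscape`.
#' @export
read_landscape_csv <- function(path, aa_order = aa_alphabet()) {
  long <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                          col_types = readr::cols(value = "c"))
  long$value <- as.numeric(long$value)  # strtod: correctly rounded
  metric <- unique(long$metric)
  stopifnot(length(metric) == 1L)
  pos <- sort(unique(long$position))
  wt <- long$wt_aa[match(pos, long$position)]
  reference <- paste0(c("P", wt), collapse = "")  # position 1 never mutated
  recs <- long[!(long$state %in% c("wild_type", "absent")), ]
  manifest <- recs[, c("position", "wt_aa", "mut_aa")]
  ls <- assemble_landscape(recs[, c("position", "mut_aa", "state", "value")],
                           metric, manifest, reference, aa_order = aa_order)
  # restore wild-type cell values exactly as stored
  wt_rows <- long[long$state == "wild_type", ]
  ls$values[cbind(match(wt_rows$mut_aa, rownames(ls$values)),
                  match(as.character(wt_rows$position), colnames(ls$values)))] <-
    wt_rows$value
  ls
}

#' Hotspot report: cells above a fold threshold
#'
#' Valued cells of a relative-activity landscape whose value exceeds
#' `fold_threshold`, grouped by position. The screen's headline threshold
#' for "significantly improved" is 5-fold.
#'
#' @param ls A relative-activity `landscape`.
#' @param fold_threshold Strict lower bound on the fold-improvement.
#' @return Tibble `position`, `wt_aa`, `mut_aa`, `value`, ordered by
#'   position; threshold kept as attribute `"threshold"`.
#' @export
find_hotspots <- function(ls, fold_threshold = 5) {
  stopifnot(inherits(ls, "landscape"))
  if (ls$metric != "relative_activity") {
    stop("hotspots are defined on the relative_activity metric", call. = FALSE)
  }
  long <- landscape_long(ls)
  hits <- long[long$state == "value" & long$value > fold_threshold, ]
  hits <- hits[order(hits$position, hits$mut_aa),
               c("position", "wt_aa", "mut_aa", "value")]
  attr(hits, "threshold") <- fold_threshold
  hits
}

#' Enantio-inversion report
#'
#' Valued cells of an e.r. landscape whose majority syn enantiomer differs
#' from the wild type's. Cell values are the 2R3S percentage of the syn
#' pair; a 50:50 cell has no majority and is never an inversion.
#'
#' @param ls An e.r. `landscape`.
#' @param wt_majority The wild-type majority label (`"2R3S"` for this
#'   enzyme, whose e.r. is 57:43).
#' @return Tibble `position`, `wt_aa`, `mut_aa`, `value`, `majority`.
#' @export
find_inversions <- function(ls, wt_majority = c("2R3S", "2S3R")) {
  stopifnot(inherits(ls, "landscape"))
  wt_majority <- match.arg(wt_majority)
  if (ls$metric != "er") {
    stop("inversions are defined on the er metric", call. = FALSE)
  }
  long <- landscape_long(ls)
  val <- long[long$state == "value", ]
  val$majority <- ifelse(val$value > 50, "2R3S",
                         ifelse(val$value < 50, "2S3R", NA_character_))
  inv <- val[!is.na(val$majority) & val$majority != wt_majority, ]
  inv[order(inv$position, inv$mut_aa),
      c("position", "wt_aa", "mut_aa", "value", "majority")]
}

#' Per-position classification summary
#'
#' Classifies every valued cell of a relative-activity landscape as
#' beneficial, neutral or detrimental under configurable fold thresholds
#' and tallies per position.
#'
#' @param ls A relative-activity `landscape`.
#' @param beneficial Strict lower bound for "beneficial" (default 2).
#' @param detrimental Strict upper bound for "detrimental" (default 0.5).
#' @return Tibble `position`, `wt_aa`, `n_beneficial`, `n_neutral`,
#'   `n_detrimental`, `n_measured`.
#' @export
position_summary <- function(ls, beneficial = 2, detrimental = 0.5) {
  stopifnot(inherits(ls, "landscape"))
  if (ls$metric != "relative_activity") {
    stop("position summary is defined on the relative_activity metric",
         call. = FALSE)
  }
  long <- landscape_long(ls)
  residues <- strsplit(ls$reference, "", fixed = TRUE)[[1L]]
  val <- long[long$state == "value", ]
  cls <- ifelse(val$value > beneficial, "beneficial",
                ifelse(val$value < detrimental, "detrimental", "neutral"))
  out <- tibble::tibble(position = ls$positions,
                        wt_aa = residues[ls$positions])
  for (cl in c("beneficial", "neutral", "detrimental")) {
    out[[paste0("n_", cl)]] <- vapply(out$position, function(p) {
      sum(val$position == p & cls == cl)
    }, integer(1L))
  }
  out$n_measured <- out$n_beneficial + out$n_neutral + out$n_detrimental
  out
}
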