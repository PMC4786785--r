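# Degenerate-codon expansion, combinatorial library enumeration, coverage
# statistics and the multiplicative additivity predictor.

IUPAC_NT <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))

#' Expand a degenerate codon
#'
#' Enumerates every concrete codon encoded by a three-letter IUPAC
#' nucleotide string, translates through the standard genetic code and
#' reports the distinct amino acids with stop codons counted separately.
#' `"NNK"` (N = ACGT, K = GT) yields 32 codons covering all 20 amino
#' acids plus the single amber stop.
#'
#' @param codon Three-letter IUPAC string, e.g. `"NNK"`.
#' @return List: `amino_acids` (sorted, stops excluded), `n_stop` (stop
#'   codon count), `n_codons`, `codons`, `translations`.
#' @export
expand_codon <- function(codon) {
  letters3 <- strsplit(toupper(codon), "", fixed = TRUE)[[1L]]
  if (length(letters3) != 3L) {
    stop("degenerate codon must have exactly 3 letters", call. = FALSE)
  }
  if (!all(letters3 %in% names(IUPAC_NT))) {
    stop("invalid IUPAC nucleotide code in '", codon, "'", call. = FALSE)
  }
  grid <- expand.grid(IUPAC_NT[[letters3[3L]]], IUPAC_NT[[letters3[2L]]],
                      IUPAC_NT[[letters3[1L]]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  codons <- paste0(grid[[3L]], grid[[2L]], grid[[1L]])
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  list(amino_acids = sort(unique(aa[aa != "*"])),
       n_stop = sum(aa == "*"),
       n_codons = length(codons),
       codons = codons,
       translations = stats::setNames(aa, codons))
}

# A design position is either an explicit amino-acid set or a degenerate
# codon string; resolve to the encoded amino-acid set (stops dropped).
resolve_position_set <- function(entry) {
  if (length(entry) == 1L && nchar(entry) == 3L &&
      all(strsplit(toupper(entry), "")[[1L]] %in% names(IUPAC_NT))) {
    return(expand_codon(entry)$amino_acids)
  }
  if (!all(entry %in% aa_alphabet())) {
    stop("invalid amino acid in design position", call. = FALSE)
  }
  sort(unique(entry))
}

#' Size of a combinatorial protein library
#'
#' Product over positions of the number of distinct amino acids allowed
#' there. Positions are given as explicit sets or degenerate codons; stop
#' codons never count towards protein variants. The screen's focused
#' library -- His-6 limited to {H,I,L,M,V}, Ala-33 to {A,D,E,Q}, Phe-50 to
#' {F,V,L,A} and full NNK degeneracy at Met-45 -- sizes to
#' 5 x 4 x 20 x 4 = 1,600.
#'
#' @param design Named list: position -> amino-acid vector or codon
#'   string.
#' @return Number of distinct protein variants (numeric).
#' @export
library_size <- function(design) {
  if (length(design) == 0L) stop("empty design", call. = FALSE)
  sets <- lapply(design, resolve_position_set)
  if (any(lengths(sets) == 0L)) {
    stop("a design position encodes no amino acids", call. = FALSE)
  }
  prod(lengths(sets))
}

#' Enumerate a combinatorial library as a variant manifest
#'
#' Expands the design into one row per distinct protein variant, labelled
#' in mutation notation relative to the reference (positions where the
#' allowed residue equals wild type contribute no mutation; the all-wild-
#' type combination is labelled `"WT"`). The output feeds the simulators,
#' closing the loop for screening a focused library in silico.
#'
#' @inheritParams library_size
#' @param reference Reference sequence string.
#' @return Tibble with `variant_id`, `n_mutations`, and one column per
#'   design position.
#' @export
enumerate_library <- function(design, reference) {
  sets <- lapply(design, resolve_position_set)
  positions <- as.integer(names(design))
  if (anyNA(positions)) stop("design names must be positions", call. = FALSE)
  grid <- expand.grid(sets, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- paste0("pos", positions)
  wt <- vapply(positions, function(p) residue_at(reference, p), character(1L))
  labels <- apply(grid, 1L, function(row) {
    mut <- row != wt
    if (!any(mut)) return("WT")
    paste(paste0(wt[mut], positions[mut], row[mut]), collapse = "/")
  })
  out <- tibble::as_tibble(grid)
  out$variant_id <- labels
  out$n_mutations <- apply(grid, 1L, function(row) sum(row != wt))
  out[, c("variant_id", "n_mutations", paste0("pos", positions))]
}

#' Collection coverage of the possible single mutants
#'
#' Percentage of all possible single substitutions (19 per position)
#' present in a manifest. Full precision is retained alongside the
#' rounded report value.
#'
#' @param manifest Collection manifest with unique variants.
#' @param positions Mutagenised positions (default 2..62).
#' @param alphabet_size Substitutions per position (19).
#' @return List: `percent` (full precision), `rounded`, `n_present`,
#'   `n_possible`.
#' @export
coverage <- function(manifest, positions = 2:62, alphabet_size = 19L) {
  key <- unique(paste0(manifest$position, manifest$mut_aa))
  n_possible <- length(positions) * alphabet_size
  pct <- 100 * length(key) / n_possible
  list(percent = pct, rounded = round(pct),
       n_present = length(key), n_possible = n_possible)
}

#' Predict a combined mutant from single-mutant effects
#'
#' Additivity heuristic for multi-mutants, tagged as model-based output:
#' on the fold scale the predicted relative activity is the product of
#' the single folds (log-additivity); an empty combination predicts the
#' wild type (1-fold).
#'
#' @param singles Named numeric: `variant_id` -> relative activity fold.
#' @param combo Character vector of single-variant ids to combine, at
#'   most one per position.
#' @param model Only `"log_additive"` is defined.
#' @return Predicted fold with attribute `"model"`.
#' @export
predict_combined <- function(singles, combo, model = "log_additive") {
  model <- match.arg(model, "log_additive")
  if (length(combo) == 0L) {
    return(structure(1, model = model))
  }
  if (!all(combo %in% names(singles))) {
    stop("combo contains a single mutant with no measured effect",
         call. = FALSE)
  }
  pos <- as.integer(sub("^[A-Z](\\d+)[A-Z]$", "\\1", combo))
  if (anyNA(pos) || anyDuplicated(pos)) {
    stop("combo must contain at most one mutation per position",
         call. = FALSE)
  }
  structure(prod(singles[combo]), model = model)
}

#' Predict the e.r. of a combined mutant
#'
#' Log-odds additivity on the enantiomer ratio: each single's shift of
#' log(2R3S/2S3R) relative to wild type is summed onto the wild-type
#' log-odds. Inputs and output are 2R3S percentages of the syn pair.
#'
#' @param singles_p Named numeric: `variant_id` -> 2R3S percentage
#'   (0 < p < 100).
#' @param combo Single-variant ids to combine, at most one per position.
#' @param wt_p Wild-type 2R3S percentage (default 57, the scaffold's
#'   57:43).
#' @return Predicted percentage pair `c(2R3S, 2S3R)` with attribute
#'   `"model"`.
#' @export
predict_combined_er <- function(singles_p, combo, wt_p = 57) {
  check <- c(wt_p, if (length(combo)) singles_p[combo])
  if (anyNA(check) || any(check <= 0) || any(check >= 100)) {
    stop("e.r. percentages must lie strictly between 0 and 100",
         call. = FALSE)
  }
  if (length(combo) > 0L) {
    pos <- as.integer(sub("^[A-Z](\\d+)[A-Z]$", "\\1", combo))
    if (anyNA(pos) || anyDuplicated(pos)) {
      stop("combo must contain at most one mutation per position",
           call. = FALSE)
    }
  }
  lo <- function(p) log(p / (100 - p))
  shift <- if (length(combo)) sum(lo(singles_p[combo]) - lo(wt_p)) else 0
  pred <- stats::plogis(lo(wt_p) + shift) * 100
  structure(c(`2R3S` = pred, `2S3R` = 100 - pred), model = "log_additive")
}
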