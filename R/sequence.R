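#' The 20 proteinogenic amino acids
#'
#' One-letter codes in alphabetical order. This is the default row order of
#' landscape matrices; figure-style orders can be supplied instead wherever
#' an `aa_order` argument is accepted.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Load the reference protein sequence
#'
#' Reads a single-record amino-acid FASTA and validates it as a screening
#' reference: one chain, standard residues only, N-terminal proline (the
#' catalytic Pro-1 of the tautomerase scaffold). The packaged default is the
#' mature 62-residue 4-oxalocrotonate tautomerase chain (Pro-1 to Arg-62).
#' All position logic downstream keys off whatever sequence is supplied
#' here, so a different scaffold can be substituted without code changes.
#'
#' @param path Path to a FASTA file. Defaults to the packaged reference.
#' @return A single string of one-letter residues (length 62 for the
#'   default); the FASTA record id is kept as attribute `"id"`.
#' @export
load_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "4ot_reference.fasta", package = "mutscape")
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) != 1L) {
    stop("reference FASTA must contain exactly one record", call. = FALSE)
  }
  seq <- as.character(set[[1L]])
  validate_reference(seq)
  attr(seq, "id") <- names(set)[1L]
  seq
}

#' Validate a reference sequence
#'
#' @param seq One-letter amino-acid string.
#' @return Invisibly, `seq`.
#' @export
validate_reference <- function(seq) {
  residues <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!all(residues %in% aa_alphabet())) {
    stop("reference contains non-standard residues", call. = FALSE)
  }
  if (residues[1L] != "P") {
    stop("reference must start with the catalytic proline (Pro-1)",
         call. = FALSE)
  }
  invisible(seq)
}

#' Residue identity at a position
#'
#' @param seq Reference sequence string.
#' @param position 1-based residue index (Pro-1 = 1).
#' @return One-letter residue code.
#' @export
residue_at <- function(seq, position) {
  n <- nchar(seq)
  if (any(position < 1L | position > n)) {
    stop("position outside 1..", n, call. = FALSE)
  }
  out <- substring(seq, position, position)
  attributes(out) <- NULL
  out
}
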