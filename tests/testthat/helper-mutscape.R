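# Shared fixtures, built in code.

REF <- load_reference()

# Residue identities the screen's numbering relies on (frozen).
CITED_RESIDUES <- c(
  `1` = "P", `2` = "I", `4` = "Q", `6` = "H", `7` = "I", `8` = "L",
  `10` = "G", `11` = "R", `12` = "S", `29` = "R", `33` = "A", `37` = "S",
  `39` = "R", `41` = "I", `45` = "M", `47` = "K", `50` = "F", `51` = "G",
  `54` = "G", `55` = "E", `56` = "L", `57` = "A", `61` = "R", `62` = "R")

# The focused library's degeneracy scheme.
FOCUSED_DESIGN <- list(`6` = c("H", "I", "L", "M", "V"),
                       `33` = c("A", "D", "E", "Q"),
                       `45` = "NNK",
                       `50` = c("F", "V", "L", "A"))

# A small manifest + landscape-record builder used by landscape tests.
toy_records <- function(manifest, value = 1, state = "value") {
  tibble::tibble(position = manifest$position, mut_aa = manifest$mut_aa,
                 state = state, value = value)
}

# Stereoisomer fractions from a d.r. (syn:anti) and an e.r. (2R3S:2S3R),
# anti enantiomers split evenly.
fractions_from_ratios <- function(dr_syn, er_2R3S) {
  syn <- dr_syn / 100
  c(syn * er_2R3S / 100, syn * (1 - er_2R3S / 100),
    (1 - syn) / 2, (1 - syn) / 2)
}
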