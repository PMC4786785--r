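Package: mutscape
Title: Mutability-Landscape Analysis for Plate-Based Enzyme Variant Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn plate-based screening of a site-saturation
    variant collection of the 62-residue enzyme 4-oxalocrotonate tautomerase
    into mutability landscapes for soluble expression, catalytic activities
    and enantioselectivity. Covers densitometric calibration of SDS-PAGE
    gels with limit-of-detection semantics, initial-rate extraction from UV
    progress curves with empty-vector background subtraction and per-plate
    wild-type normalization, chiral-HPLC peak integration with stereoisomer
    assignment and diastereomeric/enantiomeric ratios, landscape assembly
    with explicit cell states, degenerate-codon library enumeration and
    coverage statistics, a multiplicative additivity predictor for combined
    mutations, and preparative-scale stoichiometry (catalyst loading,
    fold-excess, molar yields with contaminant correction). A synthetic-data
    module emulates every raw input so the whole chain is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
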