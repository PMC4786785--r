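test_that("degenerate codons expand through the standard genetic code", {
  nnk <- expand_codon("NNK")
  expect_equal(length(nnk$amino_acids), 20L)
  expect_equal(nnk$n_stop, 1L)  # amber TAG is the only NNK stop
  expect_equal(nnk$n_codons, 32L)
  expect_true("TAG" %in% nnk$codons)

  atg <- expand_codon("ATG")
  expect_equal(atg$amino_acids, "M")
  expect_equal(atg$n_stop, 0L)
  expect_equal(atg$n_codons, 1L)

  tar <- expand_codon("TAR")  # TAA and TAG, both stops
  expect_equal(tar$amino_acids, character(0))
  expect_equal(tar$n_stop, 2L)

  expect_error(expand_codon("NXK"), "IUPAC")
  expect_error(expand_codon("NN"), "3 letters")
})

test_that("codon expansion agrees with Biostrings translation on all triplets", {
  # exhaustive oracle over the 15^3 degenerate triplets: enumerate every
  # concrete codon independently and translate with Biostrings
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  letters15 <- names(iupac)
  triplets <- expand.grid(letters15, letters15, letters15,
                          stringsAsFactors = FALSE)
  codon_sets <- lapply(seq_len(nrow(triplets)), function(r) {
    l <- unlist(triplets[r, ])
    apply(expand.grid(iupac[[l[1]]], iupac[[l[2]]], iupac[[l[3]]],
                      stringsAsFactors = FALSE),
          1, paste0, collapse = "")
  })
  # translate all 32,768 concrete codons in one call, then split back
  aa_all <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(paste(unlist(codon_sets), collapse = "")),
    no.init.codon = TRUE)), "")[[1]]
  aa_sets <- split(aa_all, rep(seq_along(codon_sets), lengths(codon_sets)))
  ok <- vapply(seq_along(codon_sets), function(r) {
    aa <- aa_sets[[r]]
    got <- expand_codon(paste0(unlist(triplets[r, ]), collapse = ""))
    identical(got$amino_acids, sort(unique(aa[aa != "*"]))) &&
      got$n_stop == sum(aa == "*") &&
      got$n_codons == length(codon_sets[[r]])
  }, logical(1))
  expect_true(all(ok))
  expect_length(ok, 15^3)
})

test_that("library size is the product of the per-position sets", {
  expect_equal(library_size(FOCUSED_DESIGN), 1600)
  expect_equal(library_size(list(`45` = "M")), 1)
  expect_equal(library_size(list(`6` = c("H", "I"), `50` = c("F", "V", "L"))), 6)
  # permutation invariance and multiplicativity under concatenation
  expect_equal(library_size(rev(FOCUSED_DESIGN)), 1600)
  expect_equal(library_size(FOCUSED_DESIGN[1:2]) *
                 library_size(FOCUSED_DESIGN[3:4]), 1600)
  expect_error(library_size(list()), "empty")
})

test_that("enumeration yields one manifest row per protein variant", {
  lib <- enumerate_library(FOCUSED_DESIGN, REF)
  expect_equal(nrow(lib), 1600L)
  expect_equal(anyDuplicated(lib$variant_id), 0L)
  expect_true("WT" %in% lib$variant_id)  # all four wild-type residues allowed
  expect_true("H6I/M45Y/F50A" %in% lib$variant_id)
  expect_equal(max(lib$n_mutations), 4L)
})

test_that("coverage reports the fraction of possible singles", {
  col <- make_collection(REF, 15, 1040, seed = 1)
  cov <- coverage(col)
  expect_equal(cov$percent, 100 * 1040 / (61 * 19), tolerance = 1e-12)
  expect_equal(cov$rounded, 90)
  expect_equal(coverage(make_collection(REF, 19, 1159, seed = 1))$percent, 100)
  empty <- col[0, ]
  expect_equal(coverage(empty)$percent, 0)
  # monotone in manifest size
  expect_lt(coverage(col[1:500, ])$percent, cov$percent)
})

test_that("additivity predictions multiply single folds", {
  singles <- c(H6I = 2, M45Y = 3, F50A = 0.5)
  expect_equal(as.numeric(predict_combined(singles, c("H6I", "M45Y"))), 6)
  expect_equal(as.numeric(predict_combined(singles, "F50A")), 0.5)
  expect_equal(as.numeric(predict_combined(singles, character(0))), 1)
  expect_identical(attr(predict_combined(singles, "H6I"), "model"),
                   "log_additive")
  expect_error(predict_combined(c(singles, H6M = 1.2), c("H6I", "H6M")),
               "one mutation")
  expect_error(predict_combined(singles, "A33D"), "no measured")
})

test_that("e.r. predictions add on the log-odds scale", {
  # empty combination returns the wild-type ratio
  expect_equal(as.numeric(predict_combined_er(c(), character(0), wt_p = 57)),
               c(57, 43))
  # a single mutation reproduces its own measurement
  singles <- c(F50A = 7, R39E = 95)
  expect_equal(predict_combined_er(singles, "F50A", wt_p = 57)[["2R3S"]], 7,
               tolerance = 1e-9)
  # two inverting mutations push further toward 2S3R than either alone
  singles2 <- c(M45Y = 20, F50A = 7)
  pred <- predict_combined_er(singles2, c("M45Y", "F50A"), wt_p = 57)
  expect_lt(pred[["2R3S"]], 7)
  expect_equal(sum(pred), 100)
  expect_error(predict_combined_er(c(X1Y = 100), "X1Y"), "between 0 and 100")
})
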