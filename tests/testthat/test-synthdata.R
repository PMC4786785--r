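test_that("shipped reference passes the cited residue-identity checks", {
  expect_equal(unname(nchar(REF)), 62L)
  for (pos in names(CITED_RESIDUES)) {
    expect_identical(residue_at(REF, as.integer(pos)),
                     unname(CITED_RESIDUES[pos]))
  }
  expect_silent(validate_reference(unname(REF)))
})

test_that("make_collection honours size, per-position minimum and determinism", {
  col <- make_collection(REF, min_per_position = 15, total = 1040, seed = 3)
  expect_equal(nrow(col), 1040L)
  counts <- table(col$position)
  expect_equal(sort(unique(col$position)), 2:62)
  expect_true(all(counts >= 15 & counts <= 19))
  expect_equal(anyDuplicated(col$variant_id), 0L)
  # substitutions are genuine and consistent with the reference
  expect_true(all(col$mut_aa != col$wt_aa))
  expect_identical(col$wt_aa, residue_at(REF, col$position))

  # saturation: every possible single present exactly once
  full <- make_collection(REF, min_per_position = 19, total = 61 * 19, seed = 1)
  expect_equal(nrow(full), 1159L)
  expect_true(all(table(full$position) == 19L))

  expect_error(make_collection(REF, 15, 900), "infeasible")
  expect_error(make_collection(REF, 19, 1200), "infeasible")

  expect_identical(make_collection(REF, 15, 1040, seed = 9),
                   make_collection(REF, 15, 1040, seed = 9))
  expect_false(identical(col, make_collection(REF, 15, 1040, seed = 4)))
})

test_that("per-position counts stay within bounds over many seeds", {
  for (s in 1:5) {
    col <- make_collection(REF, min_per_position = 15, total = 1000, seed = s)
    counts <- table(factor(col$position, levels = 2:62))
    expect_true(all(counts >= 15 & counts <= 19))
    expect_equal(anyDuplicated(paste0(col$position, col$mut_aa)), 0L)
  }
})

test_that("noise-free traces are linear-then-flat with the exact slope", {
  sp <- assay_michael_butanal()
  conv <- sp$extinction_mM_cm * sp$path_cm / 1000
  for (rate in c(0.3, 2.5, 12)) {
    tr <- simulate_trace(sp, rate, background_rate_uM_min = 0.25,
                         noise_sd = 0)
    # OLS on the early linear segment recovers the analytic slope exactly
    early <- tr[tr$absorbance > 0.9 * tr$absorbance[1], ]
    fit <- stats::lm(absorbance ~ I(time_s / 60), data = early)
    expect_equal(unname(stats::coef(fit)[2]), -(rate + 0.25) * conv,
                 tolerance = 1e-9)
    expect_true(all(tr$absorbance >= 0))
  }
  flat <- simulate_trace(sp, 0, 0, noise_sd = 0)
  expect_true(all(flat$absorbance == flat$absorbance[1]))
  # determinism under seed
  expect_identical(simulate_trace(sp, 1, 0.2, noise_sd = 0.01, seed = 5),
                   simulate_trace(sp, 1, 0.2, noise_sd = 0.01, seed = 5))
})

test_that("simulate_plate lays out duplicates and controls", {
  col <- make_collection(REF, 15, 1040, seed = 1)[1:40, ]
  truth <- make_truth(col, seed = 2)
  sp <- assay_michael_butanal()
  pl <- simulate_plate(col, truth, sp, n_wt = 4, n_ev = 4, noise_sd = 0,
                       seed = 1)
  wells <- unique(pl[, c("well", "role", "variant_id")])
  expect_equal(nrow(wells), 88L)
  expect_equal(sum(wells$role == "variant"), 80L)
  expect_equal(sum(wells$role == "wt"), 4L)
  expect_equal(sum(wells$role == "ev"), 4L)
  expect_true(all(table(wells$variant_id[wells$role == "variant"]) == 2L))
  expect_error(simulate_plate(make_collection(REF, 15, 1040, seed = 1)[1:60, ],
                              truth, sp),
               "overflow")

  # a dead variant's wells look exactly like empty-vector wells (no noise)
  dead <- col[1, ]
  t0 <- make_truth(dead, seed = 1, rel_overrides = setNames(0, dead$variant_id))
  p0 <- simulate_plate(dead, t0, sp, noise_sd = 0, seed = 1)
  a_var <- p0$absorbance[p0$role == "variant" & p0$well == p0$well[1]]
  a_ev <- p0$absorbance[p0$role == "ev"][seq_along(a_var)]
  expect_equal(a_var, a_ev, tolerance = 1e-12)
})

test_that("gel intensities are linear in load with a background intercept", {
  samples <- tibble::tibble(variant_id = c("A33D", "F50A"),
                            conc_mg_ml = c(2, 0.4))
  g <- simulate_gel(samples, gain = 1000, intercept = 50, noise_sd = 0)
  cal <- g[g$role == "calibration", ]
  expect_equal(cal$intensity, 1000 * cal$load_ug + 50)
  smp <- g[g$role == "sample", ]
  expect_true(all(is.na(smp$load_ug)))
  expect_equal(smp$intensity, 1000 * samples$conc_mg_ml * 1 + 50)
  # zero load sits at the intercept
  g0 <- simulate_gel(tibble::tibble(variant_id = "x", conc_mg_ml = 0),
                     gain = 1000, intercept = 50, noise_sd = 0)
  expect_equal(g0$intensity[g0$role == "sample"], 50)
  expect_error(simulate_gel(tibble::tibble(variant_id = letters[1:23],
                                           conc_mg_ml = 1)),
               "too many")
})

test_that("chromatogram peak areas follow the requested fractions", {
  eq <- simulate_chromatogram(rep(0.25, 4), noise_sd = 0)
  peaks <- detect_and_integrate(eq)
  expect_equal(nrow(peaks), 4L)
  expect_true(max(peaks$area) / min(peaks$area) < 1.001)
  expect_equal(peaks$area, rep(25, 4), tolerance = 1e-3)

  two <- simulate_chromatogram(c(0.5, 0.5, 0, 0), noise_sd = 0)
  expect_equal(nrow(detect_and_integrate(two)), 2L)

  # analytic Gaussian areas recovered within 0.1% for an arbitrary mix
  fr <- c(0.1, 0.55, 0.05, 0.3)
  cc <- simulate_chromatogram(fr, noise_sd = 0, total_area = 80)
  ar <- assign_stereoisomers(detect_and_integrate(cc))$areas
  expect_equal(unname(ar), 80 * fr, tolerance = 1e-3)
})
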