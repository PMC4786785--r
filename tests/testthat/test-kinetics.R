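test_that("noise-free rates are recovered exactly and flat traces give zero", {
  sp <- assay_michael_butanal()
  for (rate in c(0.25, 1, 4, 12.5)) {
    tr <- simulate_trace(sp, rate, 0, noise_sd = 0)
    est <- initial_rate(tr, sp)
    expect_equal(est$rate_uM_min, rate, tolerance = 1e-9)
    expect_equal(est$r_squared, 1, tolerance = 1e-12)
  }
  flat <- simulate_trace(sp, 0, 0, noise_sd = 0)
  est0 <- initial_rate(flat, sp)
  expect_equal(est0$rate_uM_min, 0)
  expect_error(initial_rate(flat[1:3, ], sp), "fewer than")
})

test_that("the fit window stays inside the linear phase of a two-phase trace", {
  sp <- assay_michael_butanal()
  # fast depletion: substrate gone after ~13 min of an 80-min read
  rate <- 50
  tr <- simulate_trace(sp, rate, 0, noise_sd = 0)
  kink <- which(tr$absorbance == 0)[1]
  est <- initial_rate(tr, sp)
  expect_lt(unname(est$window["end"]), kink)
  expect_equal(est$rate_uM_min, rate, tolerance = 1e-9)
})

test_that("background rate averages the empty-vector wells of the plate", {
  sp <- assay_michael_butanal()
  mk <- function(rate, well) {
    tr <- simulate_trace(sp, 0, rate, noise_sd = 0)
    tibble::tibble(plate_id = "P", well = well, role = "ev",
                   variant_id = NA, time_s = tr$time_s,
                   absorbance = tr$absorbance)
  }
  plate <- dplyr::bind_rows(mk(1, "A1"), mk(3, "A2"))
  expect_equal(background_rate(plate, sp), 2, tolerance = 1e-9)
  expect_error(background_rate(plate[plate$well == "none", ], sp),
               "no empty-vector")
})

test_that("specific activity applies states and recovers known truth", {
  sp <- assay_michael_butanal()
  # rate equal to background: zero activity
  z <- specific_activity(0.25, 0.25, 2, FALSE, sp)
  expect_identical(z$state, "zero_activity")
  expect_equal(z$specific_activity, 0)
  # below-LOD expression dominates any rate
  b <- specific_activity(5, 0.25, 0.3, TRUE, sp)
  expect_identical(b$state, "below_lod")
  expect_true(is.na(b$specific_activity))
  # known U/mg round trip, noise-free
  rate <- 4.75
  v <- specific_activity(rate + 0.25, 0.25, 2, FALSE, sp)
  u_expected <- rate * sp$well_volume_ml / 1000
  expect_equal(v$U, u_expected, tolerance = 1e-6)
  expect_equal(v$specific_activity,
               u_expected / (2 * sp$cfe_fraction * sp$well_volume_ml),
               tolerance = 1e-6)
})

test_that("plate normalization matches a brute-force oracle on a toy plate", {
  sp <- assay_michael_butanal()
  col <- make_collection(REF, 15, 1040, seed = 2)[1:3, ]
  truth <- make_truth(col, seed = 3,
                      rel_overrides = setNames(c(3.5, 0.5, 1), col$variant_id))
  plate <- simulate_plate(col, truth, sp, n_wt = 2, n_ev = 2, noise_sd = 0,
                          seed = 1)
  expr <- tibble::tibble(variant_id = col$variant_id,
                         conc_mg_ml = truth$true_conc, below_lod = FALSE)
  rec <- analyze_plate(plate, sp, expr, wt_conc_mg_ml = 2)

  # oracle: explicit per-well division, no shared code path
  rate_of <- function(df) {
    seg <- df[df$absorbance >= df$absorbance[1] * 0.8, ]
    f <- stats::lm(absorbance ~ I(time_s / 60), data = seg)
    -unname(stats::coef(f)[2]) * 1000 / (sp$extinction_mM_cm * sp$path_cm)
  }
  wells <- split(plate, plate$well)
  roles <- vapply(wells, function(w) w$role[1], character(1))
  ids <- vapply(wells, function(w) w$variant_id[1], character(1))
  rates <- vapply(wells, rate_of, numeric(1))
  bg <- mean(rates[roles == "ev"])
  sa <- function(rate, conc) (rate - bg) / conc
  wt_ref <- mean(sa(rates[roles == "wt"], 2))
  for (v in col$variant_id) {
    vr <- mean(rates[!is.na(ids) & ids == v])  # duplicates, noise-free
    expected <- sa(vr, truth$true_conc[truth$variant_id == v]) / wt_ref
    got <- rec$relative[!is.na(rec$variant_id) & rec$variant_id == v]
    expect_equal(got, expected, tolerance = 1e-6)
  }
})

test_that("relative activities are invariant to extinction and path length", {
  sp <- assay_michael_butanal()
  col <- make_collection(REF, 15, 1040, seed = 5)[1:4, ]
  truth <- make_truth(col, seed = 6)
  plate <- simulate_plate(col, truth, sp, noise_sd = 0.003, seed = 8)
  expr <- tibble::tibble(variant_id = col$variant_id,
                         conc_mg_ml = truth$true_conc, below_lod = FALSE)
  sp2 <- sp
  sp2$extinction_mM_cm <- sp$extinction_mM_cm * 2.31
  sp2$path_cm <- sp$path_cm * 0.57
  r1 <- analyze_plate(plate, sp, expr)
  r2 <- analyze_plate(plate, sp2, expr)
  expect_equal(r1$relative, r2$relative, tolerance = 1e-12)
  expect_identical(r1$state, r2$state)
})

test_that("records are unchanged by the order plates are processed in", {
  sp <- assay_michael_butanal()
  col <- make_collection(REF, 15, 1040, seed = 7)
  a <- col[1:3, ]; b <- col[4:6, ]
  truth <- make_truth(col[1:6, ], seed = 7)
  expr <- tibble::tibble(variant_id = truth$variant_id,
                         conc_mg_ml = truth$true_conc, below_lod = FALSE)
  pa <- simulate_plate(a, truth, sp, plate_id = "PA", seed = 1)
  pb <- simulate_plate(b, truth, sp, plate_id = "PB", seed = 2,
                       wt_rate_uM_min = 4)  # different plate-level reference
  one <- dplyr::bind_rows(analyze_plate(pa, sp, expr),
                          analyze_plate(pb, sp, expr))
  other <- dplyr::bind_rows(analyze_plate(pb, sp, expr),
                            analyze_plate(pa, sp, expr))
  key <- function(x) x[order(x$plate_id, x$role, x$variant_id), ]
  expect_equal(key(one)$relative, key(other)$relative)
})

test_that("true activity ratios across the assay's dynamic range are recovered", {
  # the assay resolves five-fold decreased to five-fold increased activity
  sp <- assay_michael_butanal()
  ratios <- c(0.2, 0.5, 1, 2, 3.5, 5)
  col <- make_collection(REF, 15, 1040, seed = 11)[1:6, ]
  rec_ratio <- sapply(1:3, function(s) {
    truth <- make_truth(col, seed = s,
                        rel_overrides = setNames(ratios, col$variant_id))
    plate <- simulate_plate(col, truth, sp, noise_sd = 0.003, seed = 20 + s)
    expr <- tibble::tibble(variant_id = col$variant_id,
                           conc_mg_ml = truth$true_conc, below_lod = FALSE)
    out <- analyze_plate(plate, sp, expr)
    out$relative[match(col$variant_id, out$variant_id)] / ratios
  })
  expect_true(all(abs(apply(rec_ratio, 1, stats::median) - 1) < 0.1))
})
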