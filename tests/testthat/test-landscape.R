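test_that("assembly produces one cell per substitution with state accounting", {
  man <- make_collection(REF, 15, 1040, seed = 1)
  empty <- tibble::tibble(position = integer(), mut_aa = character(),
                          state = character(), value = numeric())
  ls0 <- assemble_landscape(empty, "relative_activity", man, REF)
  tab0 <- table(factor(ls0$states, levels = c("wild_type", "absent")))
  expect_equal(unname(tab0[["wild_type"]]), 61L)
  expect_equal(sum(tab0), 20L * 61L)
  # wild-type cells of a relative-activity landscape carry 1
  expect_true(all(ls0$values[ls0$states == "wild_type"] == 1))

  # a full record set addresses exactly the 1,040 manifest cells
  ls1 <- assemble_landscape(toy_records(man, value = 1), "relative_activity",
                            man, REF)
  expect_equal(sum(!(ls1$states %in% c("wild_type", "absent"))), 1040L)

  # conservation: states always tile the full 20 x 61 grid
  expect_equal(length(ls1$states), 20L * 61L)

  dup <- dplyr::bind_rows(toy_records(man[1, ]), toy_records(man[1, ]))
  expect_error(assemble_landscape(dup, "relative_activity", man, REF),
               "duplicate")
  ghost <- tibble::tibble(position = man$position[1],
                          mut_aa = setdiff(aa_alphabet(),
                                           c(man$mut_aa[man$position == man$position[1]],
                                             man$wt_aa[1]))[1],
                          state = "value", value = 1)
  expect_error(assemble_landscape(ghost, "relative_activity", man, REF),
               "not in the collection")
})

test_that("landscape CSV round trip is the identity", {
  man <- make_collection(REF, 15, 1040, seed = 2)
  vals <- withr::with_seed(3, stats::runif(nrow(man), 0, 4))
  rec <- toy_records(man, value = vals)
  rec$state[1:5] <- "below_lod"; rec$value[1:5] <- NA
  rec$state[6:8] <- "zero_activity"; rec$value[6:8] <- 0
  ls <- assemble_landscape(rec, "relative_activity", man, REF)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape_csv(ls, path)
  back <- read_landscape_csv(path)
  expect_identical(back$states, ls$states)
  expect_identical(back$values, ls$values)
  expect_identical(back$metric, ls$metric)
})

test_that("hotspot detection matches planted improvements and is monotone", {
  man <- make_collection(REF, 19, 61 * 19, seed = 1)
  planted <- c(2, 4, 8, 37, 50)  # positions with >5-fold improvements
  rec <- toy_records(man, value = 1)
  for (p in planted) {
    i <- which(rec$position == p)[1:2]
    rec$value[i] <- c(6, 8)
  }
  ls <- assemble_landscape(rec, "relative_activity", man, REF)
  hs <- find_hotspots(ls, fold_threshold = 5)
  expect_equal(sort(unique(hs$position)), planted)
  expect_equal(nrow(hs), 10L)

  expect_equal(nrow(find_hotspots(ls, Inf)), 0L)
  all_valued <- find_hotspots(ls, 0)
  expect_equal(nrow(all_valued), sum(ls$states == "value"))

  # monotone in the threshold
  for (t2 in c(0.5, 2, 7)) {
    lo <- find_hotspots(ls, 0.3)
    hi <- find_hotspots(ls, t2)
    expect_true(all(paste0(hi$position, hi$mut_aa) %in%
                      paste0(lo$position, lo$mut_aa)))
  }
})

test_that("inversion detection flips on the majority enantiomer only", {
  man <- make_collection(REF, 19, 61 * 19, seed = 1)
  rec <- toy_records(man[1:4, ], value = c(57, 7, 50, 93))
  ls <- assemble_landscape(rec, "er", man, REF, wt_value = 57)
  inv <- find_inversions(ls, wt_majority = "2R3S")
  expect_equal(nrow(inv), 1L)  # only the 7:93 cell flips; 50:50 does not
  expect_equal(inv$value, 7)
  expect_identical(inv$majority, "2S3R")

  same <- assemble_landscape(toy_records(man[1:6, ], value = 57), "er",
                             man, REF, wt_value = 57)
  expect_equal(nrow(find_inversions(same, "2R3S")), 0L)
})

test_that("position summary classifies under the configured thresholds", {
  man <- make_collection(REF, 19, 61 * 19, seed = 1)
  ls1 <- assemble_landscape(toy_records(man, value = 1),
                            "relative_activity", man, REF)
  s1 <- position_summary(ls1)
  expect_true(all(s1$n_neutral == 19L))
  expect_true(all(s1$n_beneficial == 0L) && all(s1$n_detrimental == 0L))

  one <- assemble_landscape(toy_records(man[man$variant_id == "A33D", ],
                                        value = 3.5),
                            "relative_activity", man, REF)
  s2 <- position_summary(one)
  expect_equal(sum(s2$n_beneficial), 1L)
  expect_equal(s2$n_beneficial[s2$position == 33], 1L)

  empty <- tibble::tibble(position = integer(), mut_aa = character(),
                          state = character(), value = numeric())
  s3 <- position_summary(assemble_landscape(empty, "relative_activity",
                                            man, REF))
  expect_true(all(s3$n_measured == 0L))
})
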