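test_that("absent filter removes exactly the all-absent probes", {
  intensity <- matrix(200, 3, 5, dimnames = list(c("a", "b", "c"), NULL))
  calls <- rbind(rep("A", 5),            # all absent -> removed
                 c("A", "A", "P", "A", "A"),  # one P -> retained
                 rep("P", 5))
  ds <- toy_dataset(intensity, calls)
  suppressMessages(out <- filter_absent(ds))
  expect_identical(probe_ids(out), c("b", "c"))
  expect_identical(attr(out, "removed"), "a")
  expect_identical(out$intensity["b", ], ds$intensity["b", ])
})

test_that("unknown call symbols are rejected naming probe and sample", {
  intensity <- matrix(200, 1, 5, dimnames = list("p1", NULL))
  calls <- matrix(c("P", "P", "X", "P", "P"), 1)
  expect_error(toy_dataset(intensity, calls), "p1")
})

test_that("low-expression filter keeps probes with one week at the floor", {
  intensity <- rbind(c(50, 60, 70, 80, 90),     # all below -> removed
                     c(99, 99, 99, 99, 100),    # one at floor -> retained
                     c(500, 500, 500, 500, 500))
  ds <- toy_dataset(intensity)
  suppressMessages(out <- filter_low_expression(ds))
  expect_identical(probe_ids(out), c("p002", "p003"))
  expect_identical(attr(out, "removed"), "p001")
})

test_that("medians follow the standard convention for odd and even counts", {
  intensity <- matrix(c(1, 2, 3, 4, 100), 1)
  ds5 <- toy_dataset(intensity, weeks = 1, reps = 5)
  expect_equal(unname(median_by_timepoint(ds5)[1, 1]), 3)
  ds4 <- toy_dataset(matrix(c(1, 2, 3, 4), 1), weeks = 1, reps = 4)
  expect_equal(unname(median_by_timepoint(ds4)[1, 1]), 2.5)
  dsc <- toy_dataset(matrix(7, 1, 4), weeks = 1, reps = 4)
  expect_equal(unname(median_by_timepoint(dsc)[1, 1]), 7)
})

test_that("log2 ratio profiles match hand arithmetic and flag bad input", {
  med <- median_by_timepoint(toy_dataset(rbind(
    c(100, 200, 400, 800, 1600),
    c(300, 300, 300, 300, 300),
    c(100, 50, 25, 100, 100))))
  prof <- log2_ratio_profiles(med)
  expect_equal(unname(prof[1, ]), c(1, 2, 3, 4))
  expect_equal(unname(prof[2, ]), c(0, 0, 0, 0))
  expect_equal(unname(prof[3, ]), c(-1, -2, 0, 0))
  expect_identical(colnames(prof), c("2", "4", "8", "16"))
  med_bad <- med
  med_bad[2, 3] <- 0
  expect_error(log2_ratio_profiles(med_bad), "p002")
  # include_baseline appends the identically-zero column
  prof_b <- log2_ratio_profiles(med, include_baseline = TRUE)
  expect_equal(unname(prof_b[, "1"]), c(0, 0, 0))
})

test_that("filter bookkeeping is exact and composes", {
  cfg <- sim_config(400, list(list(coef = 0, size = 400)),
                    absent_fraction = 0.25, low_floor_fraction = 0.2,
                    seed = 9)
  g <- generate_expression_dataset(cfg)
  suppressMessages(pp <- preprocess_dataset(g$dataset))
  expect_identical(pp$n_all_absent, as.integer(round(0.25 * 400)))
  expect_identical(pp$n_below_floor,
                   as.integer(round(0.2 * (400 - pp$n_all_absent))))
  expect_identical(pp$n_initial,
                   pp$n_all_absent + pp$n_below_floor + pp$n_retained)
})

test_that("permuting sample columns changes no median or filter decision", {
  cfg <- recovery_config(seed = 13, n_probes = 60)
  g <- generate_expression_dataset(cfg)
  ds <- g$dataset
  set.seed(1)
  perm <- sample(ncol(ds$intensity))
  ds_p <- expression_dataset(ds$intensity[, perm], ds$calls[, perm],
                             ds$samples[perm, ])
  expect_equal(median_by_timepoint(ds), median_by_timepoint(ds_p))
  suppressMessages({
    expect_identical(probe_ids(filter_absent(ds)), probe_ids(filter_absent(ds_p)))
    expect_identical(probe_ids(filter_low_expression(ds)),
                     probe_ids(filter_low_expression(ds_p)))
  })
})

test_that("global intensity scaling shifts medians but cancels in log2 ratios", {
  cfg <- recovery_config(seed = 17, n_probes = 40)
  ds <- generate_expression_dataset(cfg)$dataset
  k <- 3.7
  ds_k <- expression_dataset(ds$intensity * k, ds$calls, ds$samples)
  expect_equal(median_by_timepoint(ds_k), median_by_timepoint(ds) * k)
  expect_equal(log2_ratio_profiles(median_by_timepoint(ds_k)),
               log2_ratio_profiles(median_by_timepoint(ds)))
})
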