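ihc_rows <- function(rat, group, week, e1, e2) {
  do.call(rbind, lapply(seq_along(e1), function(f)
    data.frame(rat = rat, group = group, week = week, field = f,
               examiner = c("E1", "E2"), percent = c(e1[f], e2[f]),
               stringsAsFactors = FALSE)))
}

test_that("field scoring averages examiners and drops the most discordant field", {
  tab <- ihc_rows("r1", "immobilized", 2,
                  e1 = c(50, 60, 70, 80), e2 = c(55, 60, 90, 80))
  fs <- score_fields(tab)
  expect_equal(fs$mean, c(52.5, 60, 80, 80))
  expect_equal(fs$inter_rater_diff, c(5, 0, 20, 0))
  expect_identical(fs$field[fs$removed], 3L)
  expect_equal(fs$mean[!fs$removed], c(52.5, 60, 80))
})

test_that("ties remove the lowest field index and 2-field rats keep one", {
  tied <- ihc_rows("r1", "sham", 4, e1 = c(10, 20, 30, 40),
                   e2 = c(10, 20, 30, 40))
  fs <- score_fields(tied)
  expect_identical(fs$field[fs$removed], 1L)
  expect_identical(sum(!fs$removed), 3L)
  two <- ihc_rows("r2", "sham", 4, e1 = c(10, 20), e2 = c(12, 20))
  fs2 <- score_fields(two)
  expect_identical(sum(!fs2$removed), 1L)
})

test_that("a field without exactly two examiner rows is rejected", {
  bad <- ihc_rows("r1", "sham", 2, e1 = c(10, 20), e2 = c(12, 22))[-1, ]
  expect_error(score_fields(bad), "exactly 2 examiner rows")
  oob <- ihc_rows("r1", "sham", 2, e1 = c(10, 101), e2 = c(12, 90))
  expect_error(score_fields(oob), "\\[0, 100\\]")
})

test_that("worst-field removal never increases a rat's mean inter-rater difference", {
  set.seed(6)
  for (i in 1:20) {
    tab <- ihc_rows("r1", "sham", 2, e1 = runif(4, 0, 100),
                    e2 = runif(4, 0, 100))
    fs <- score_fields(tab)
    expect_lte(mean(fs$inter_rater_diff[!fs$removed]),
               mean(fs$inter_rater_diff))
  }
})

test_that("all-tied groups give H = 0 and p = 1", {
  tab <- rbind(ihc_rows("r1", "sham", 2, rep(30, 4), rep(30, 4)),
               ihc_rows("r2", "immobilized", 2, rep(30, 4), rep(30, 4)))
  res <- kruskal_wallis_by_week(score_fields(tab))
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)
  expect_false(res$significant)
})

test_that("H and the exact permutation p match first-principles enumeration", {
  # separated toy groups: sham (1,2,3) vs immobilized (10,11,12)
  tab <- rbind(ihc_rows("r1", "sham", 8, c(1, 2, 3, 50), c(1, 2, 3, 90)),
               ihc_rows("r2", "immobilized", 8, c(10, 11, 12, 50),
                        c(10, 11, 12, 90)))
  res <- kruskal_wallis_by_week(score_fields(tab), exact = TRUE)
  vals <- c(1, 2, 3, 10, 11, 12)
  grp <- rep(c("sham", "immobilized"), each = 3)
  expect_equal(res$H, manual_kw_H(vals, grp))
  expect_equal(res$H, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2))
  # both extreme splits of the 20 attain the maximal H
  expect_equal(res$p_exact, perm_kw_p(vals, grp))
  expect_equal(res$p_exact, 2 / 20)
  # the chi-square approximation is in the documented ballpark
  expect_equal(res$p, pchisq(res$H, df = 1, lower.tail = FALSE))
})

test_that("duplicated values change H only through the tie correction", {
  grp <- rep(c("a", "b"), each = 3)
  tie_vals <- c(1, 2, 3, 3, 11, 12)   # value 3 duplicated across groups
  tab <- rbind(ihc_rows("r1", "sham", 4, c(1, 2, 3, 50), c(1, 2, 3, 90)),
               ihc_rows("r2", "immobilized", 4, c(3, 11, 12, 50),
                        c(3, 11, 12, 90)))
  res <- kruskal_wallis_by_week(score_fields(tab))
  expect_equal(res$H, manual_kw_H(tie_vals, grp))
})

test_that("H is invariant under strictly monotone transforms of the scores", {
  set.seed(12)
  tab <- generate_ihc_dataset(4, ihc_effects(40, 20, weeks = 2),
                              examiner_sd = 3, seed = 44)
  fs <- score_fields(tab)
  h1 <- kruskal_wallis_by_week(fs)$H
  fs_t <- fs
  fs_t$mean <- exp(fs$mean / 25)     # strictly increasing transform
  h2 <- kruskal_wallis_by_week(fs_t)$H
  expect_equal(h1, h2)
})

test_that("weeks missing a group are skipped with a warning", {
  tab <- rbind(ihc_rows("r1", "sham", 2, c(10, 20, 30, 40), c(10, 20, 30, 40)),
               ihc_rows("r2", "immobilized", 2, c(15, 25, 35, 45),
                        c(15, 25, 35, 45)),
               ihc_rows("r3", "sham", 4, c(10, 20, 30, 40), c(10, 20, 30, 40)))
  expect_warning(res <- kruskal_wallis_by_week(score_fields(tab)),
                 "only one group")
  expect_identical(res$week, 2)
})
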