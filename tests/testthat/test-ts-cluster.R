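cfg <- cluster_config()

test_that("inclusion filter uses a strict 2-fold boundary", {
  pr <- profiles(c(0.5, 0.9, -0.2, 0.1),
                 c(1.2, 0, 0, 0),
                 c(-1.0001, 0, 0, 0),
                 c(-1.0, 0, 0, 0))
  kept <- inclusion_filter(pr, cfg)
  expect_identical(rownames(kept), c("p002", "p003"))
})

test_that("closed-form evidence matches independent integration oracles", {
  cfg0 <- cluster_config(polynomial_order = 0)
  Y <- profiles(c(0, 0, 0, 0))
  # order-0 model against a dense-grid double integration over (beta, sigma2)
  expect_equal(marginal_log_likelihood(Y, cfg0), grid_logml_order0(Y),
               tolerance = 1e-3)
  Y2 <- profiles(c(1, 2, 1.5, 0.5), c(0.8, 1.9, 1.4, 0.6))
  expect_equal(marginal_log_likelihood(Y2, cfg0), grid_logml_order0(Y2),
               tolerance = 1e-3)
  # order-3 model against Gaussian-marginalized + 1-D quadrature oracle
  for (Y in list(Y, Y2, profiles(c(-2, 1, 0.5, 0)))) {
    expect_equal(marginal_log_likelihood(Y, cfg),
                 mvn_logml(Y, NB_WEEKS, 3), tolerance = 1e-6)
  }
})

test_that("evidence is finite for saturated singletons and order-invariant", {
  # order 3 on 4 points is saturated per series; the proper prior keeps the
  # evidence finite
  v <- profiles(c(3, -2, 1, 0.5))
  expect_true(is.finite(marginal_log_likelihood(v, cfg)))
  set.seed(11)
  Y <- profiles(rnorm(4), rnorm(4), rnorm(4), rnorm(4))
  for (perm in list(c(2, 1, 3, 4), c(4, 3, 2, 1), sample(4))) {
    expect_equal(marginal_log_likelihood(Y[perm, ], cfg),
                 marginal_log_likelihood(Y, cfg))
  }
})

test_that("merging identical profiles is favored, opposite profiles are not", {
  v <- c(2, 1, 0.5, 0)
  same <- profiles(v, v)
  opp <- profiles(v, -v)
  lm1 <- marginal_log_likelihood(profiles(v), cfg)
  expect_gt(marginal_log_likelihood(same, cfg) - 2 * lm1, 0)
  expect_lt(marginal_log_likelihood(opp, cfg) - 2 * lm1, 0)
  expect_length(agglomerate(same, cfg)$clusters, 1L)
  expect_length(agglomerate(opp, cfg)$clusters, 2L)
})

test_that("merge trace has strictly positive Bayes factors and a monotone score", {
  set.seed(5)
  Y <- profiles(t(replicate(6, c(2, 2.5, 1.5, 1) + rnorm(4, 0, 0.1))),
                t(replicate(6, c(-2, -1, -2.5, -1.5) + rnorm(4, 0, 0.1))))
  part <- agglomerate(Y, cfg)
  expect_true(all(part$trace$log_bayes_factor > 0))
  # replaying the trace, the total score never decreases
  singles <- vapply(seq_len(nrow(Y)), function(i)
    marginal_log_likelihood(Y[i, , drop = FALSE], cfg), numeric(1))
  score <- sum(singles)
  for (b in part$trace$log_bayes_factor) {
    expect_gte(score + b, score)
    score <- score + b
  }
  expect_equal(score, part$score)
})

test_that("cluster memberships are invariant to input row order", {
  set.seed(19)
  Y <- profiles(t(replicate(5, c(1.5, 2, 1, 0.5) + rnorm(4, 0, 0.15))),
                t(replicate(5, c(-1.5, -2, -1, -0.5) + rnorm(4, 0, 0.15))),
                t(replicate(4, c(2, -1.5, 1.5, 0) + rnorm(4, 0, 0.15))))
  ref <- lapply(agglomerate(Y, cfg)$clusters, `[[`, "members")
  for (i in 1:3) {
    perm <- sample(nrow(Y))
    got <- lapply(agglomerate(Y[perm, ], cfg)$clusters, `[[`, "members")
    expect_identical(got, ref)
  }
})

test_that("centers are member means, idempotent, and near planted truth", {
  Y <- profiles(c(1, 1, 1, 1), c(3, 3, 3, 3))
  fake <- structure(list(clusters = list(list(members = c("p001", "p002"))),
                         profiles = Y, weeks = NB_WEEKS),
                    class = "partition")
  expect_equal(unname(cluster_centers(fake)$clusters[[1]]$center),
               c(2, 2, 2, 2))
  singleton <- agglomerate(profiles(c(1, 0, -1, 2)), cfg)
  expect_equal(unname(singleton$clusters[[1]]$center), c(1, 0, -1, 2))
  expect_equal(cluster_centers(singleton), singleton)
  # planted-center recovery within 3 standard errors
  cfg_sim <- sim_config(40, list(list(coef = c(2, 1, 0, 0), size = 40)),
                        replicate_noise_sd = 0.1, seed = 31)
  g <- generate_expression_dataset(cfg_sim)
  ratios <- log2_ratio_profiles(median_by_timepoint(g$dataset))
  ctr <- colMeans(ratios)
  se <- apply(ratios, 2, sd) / sqrt(nrow(ratios))
  expect_true(all(abs(ctr - g$truth$centers[1, ]) < 3 * pmax(se, 0.02)))
})

test_that("selection flags follow the strict |center| > threshold rule", {
  Y <- profiles(c(0.5, 0.9, -0.2, 0.1), c(-1.3, -0.5, 0, 0))
  part <- select_clusters(agglomerate(Y, cfg), threshold = 1)
  sel <- vapply(part$clusters, `[[`, TRUE, "selected")
  ctrs <- lapply(part$clusters, `[[`, "center")
  expect_identical(sel, vapply(ctrs, function(ctr) max(abs(ctr)) > 1, TRUE))
  expect_identical(sort(selected_probes(part)), "p002")
})

test_that("trend classification separates increased, decreased and variable", {
  expect_identical(classify_trend(c(0.2, 0.8, 1.5, 2.0)), "increased")
  expect_identical(classify_trend(c(-0.1, -1.2, -2.0, -1.8)), "decreased")
  expect_identical(classify_trend(c(1.5, -1.5, 1.0, 0)), "variable")
  expect_identical(classify_trend(c(0.1, 0.2, 0.9, 0.5)), "variable")
})

test_that("partition summary carries sizes, centers, evidence and flags", {
  set.seed(2)
  Y <- profiles(t(replicate(3, c(2, 1.5, 1, 0.5) + rnorm(4, 0, 0.05))),
                t(replicate(3, c(-2, -1.5, -1, -0.5) + rnorm(4, 0, 0.05))))
  part <- classify_partition_trends(select_clusters(agglomerate(Y, cfg)))
  summ <- partition_summary(part)
  expect_identical(nrow(summ), length(part$clusters))
  expect_identical(sum(summ$size), nrow(Y))
  expect_true(all(c("logml", "selected", "trend") %in% names(summ)))
  expect_setequal(summ$trend, c("increased", "decreased"))
})
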