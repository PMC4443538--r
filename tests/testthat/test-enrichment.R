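bg20 <- sprintf("G%02d", 1:20)

test_that("hypergeometric tail matches brute-force enumeration of draws", {
  # N = 20, K = 5, n = 5, all achievable k: compare P(X >= k) against
  # counting every C(20,5) query draw
  coll <- gene_set_collection(list(term = bg20[1:5]))
  for (k in 0:5) {
    query <- c(bg20[seq_len(k)], bg20[5 + seq_len(5 - k)])
    res <- hypergeometric_enrichment(query, bg20, coll)
    expect_identical(res$k, k)
    expect_equal(res$p, brute_hyper_tail(k, K = 5, N = 20, n = 5),
                 tolerance = 1e-12)
  }
})

test_that("degenerate full overlap gives p = 1", {
  coll <- gene_set_collection(list(all = bg20))
  res <- hypergeometric_enrichment(bg20, bg20, coll)
  expect_equal(res$p, 1)
})

test_that("EASE boundary: a single-gene overlap is never significant", {
  coll <- gene_set_collection(list(term = bg20[1:5]))
  res <- hypergeometric_enrichment(c(bg20[1], bg20[6:9]), bg20, coll)
  expect_identical(res$k, 1L)
  expect_equal(res$p_ease, 1)
})

test_that("EASE is conservative and q-values are BH across the collection", {
  set.seed(8)
  bg <- sprintf("G%03d", 1:200)
  coll <- gene_set_collection(lapply(setNames(1:15, paste0("t", 1:15)),
                                     function(i) sample(bg, 10 + i)))
  res <- hypergeometric_enrichment(sample(bg, 30), bg, coll)
  expect_true(all(res$p_ease >= res$p))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_false(is.unsorted(res$p))
})

test_that("p-values are invariant under consistent gene relabeling", {
  bg <- sprintf("G%03d", 1:50)
  coll <- gene_set_collection(list(a = bg[1:12], b = bg[10:30]))
  query <- bg[c(1:6, 20:25)]
  relabel <- setNames(sprintf("X%03d", 1:50), bg)
  res1 <- hypergeometric_enrichment(query, bg, coll)
  res2 <- hypergeometric_enrichment(
    unname(relabel[query]), unname(relabel),
    gene_set_collection(lapply(coll, function(g) unname(relabel[g]))))
  expect_equal(res1$p, res2$p)
})

test_that("query genes outside the background are dropped with a warning", {
  coll <- gene_set_collection(list(term = bg20[1:5]))
  expect_warning(res <- hypergeometric_enrichment(c(bg20[1:3], "NOPE"),
                                                  bg20, coll),
                 "outside the background")
  expect_identical(res$n, 3L)
  expect_error(hypergeometric_enrichment(bg20[1], character(), coll),
               "empty background")
})

test_that("cluster cross-tabulation counts genes once per cluster", {
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    gene = c("g1", "g2", "g2", "g3"))
  part <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                     cluster = c(4, 1, 4, 2))
  coll <- gene_set_collection(list(term = c("g1", "g2", "zz")))
  res <- hypergeometric_enrichment(c("g1", "g2"), c("g1", "g2", "g3", "zz"),
                                   coll)
  res <- crosstab_clusters(res, part, map)
  bd <- res$cluster_breakdown[[1]]
  expect_identical(bd[["4"]], 2L)  # g1 (p1) and g2 (p3) both reach cluster 4
  expect_identical(bd[["1"]], 1L)  # g2 also has a probe in cluster 1
  expect_identical(res$modal_cluster, "4")
  expect_equal(res$modal_pct, 100)
})

test_that("modal percentages round to whole percent", {
  genes <- sprintf("g%02d", 1:36)
  map <- data.frame(probe_id = sprintf("p%02d", 1:36), gene = genes)
  part <- data.frame(probe_id = map$probe_id,
                     cluster = c(rep(4, 24), rep(1, 12)))
  coll <- gene_set_collection(list(bp = genes))
  res <- crosstab_clusters(
    hypergeometric_enrichment(genes, c(genes, "pad"), coll), part, map)
  expect_identical(res$modal_cluster, "4")
  expect_equal(res$modal_pct, 67)   # 24 of 36
})

test_that("empty overlap yields an empty breakdown", {
  coll <- gene_set_collection(list(term = "zz"))
  map <- data.frame(probe_id = "p1", gene = "g1")
  part <- data.frame(probe_id = "p1", cluster = 1)
  res <- crosstab_clusters(
    hypergeometric_enrichment("g1", c("g1", "zz"), coll), part, map)
  expect_length(res$cluster_breakdown[[1]], 0)
  expect_true(is.na(res$modal_cluster))
})

test_that("GMT reading produces a named collection", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  coll <- read_gmt(path, "demo")
  expect_identical(names(coll), c("setA", "setB"))
  expect_setequal(coll$setB, c("g2", "g4"))
  expect_identical(attr(coll, "source"), "demo")
  expect_error(read_gmt(file.path(tempdir(), "missing.gmt")), "not found")
})
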