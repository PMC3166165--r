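test_that("hypergeometric tail matches the exact combinatorial value", {
  gsc <- gene_set_collection(list(S = letters[1:5]),
                             universe = letters[1:10])
  res <- hypergeom_enrich(letters[2:5], gsc)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-15)
  expect_equal(res[, c("N", "K", "n", "k")],
               data.frame(N = 10L, K = 5L, n = 4L, k = 4L),
               ignore_attr = TRUE)
  expect_false(res$passes)
  expect_true(hypergeom_enrich(letters[2:5], gsc,
                               threshold = 0.05)$passes)

  # disjoint set: dropped at the default min_overlap, degenerate p = 1
  # when k = 0 is allowed to be reported
  gsc2 <- gene_set_collection(list(S = c("x", "y", "z")),
                              universe = c(letters[1:6], "x", "y", "z"))
  expect_equal(nrow(hypergeom_enrich(letters[1:3], gsc2)), 0L)
  res0 <- hypergeom_enrich(letters[1:3], gsc2, min_overlap = 0L)
  expect_equal(res0$p_value, 1)
})

test_that("hypergeometric p agrees with exhaustive draw enumeration (N <= 12)", {
  set.seed(21)
  cases <- 0L
  for (i in 1:40) {
    N <- sample(5:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    universe <- sprintf("u%02d", seq_len(N))
    gsc <- gene_set_collection(list(S = universe[seq_len(K)]),
                               universe = universe)
    query <- sample(universe, n)
    res <- hypergeom_enrich(query, gsc, min_overlap = 0L)
    k <- res$k
    expect_equal(res$p_value, oracle_hypergeom(N, K, n, k),
                 tolerance = 1e-12)
    cases <- cases + 1L
  }
  expect_equal(cases, 40L)

  # the all-overlap corner: query = set = half the universe
  gsc <- gene_set_collection(list(S = sprintf("u%02d", 1:5)),
                             universe = sprintf("u%02d", 1:10))
  res <- hypergeom_enrich(sprintf("u%02d", 1:5), gsc)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-15)
  expect_equal(res$p_value, oracle_hypergeom(10, 5, 5, 5), tolerance = 1e-15)
})

test_that("p is monotone in the overlap and equals one-sided Fisher", {
  N <- 60L; K <- 12L; n <- 15L
  p_at <- function(k) phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  universe <- sprintf("u%02d", seq_len(N))
  prev <- Inf
  for (k in 1:min(K, n)) {
    gsc <- gene_set_collection(list(S = universe[seq_len(K)]),
                               universe = universe)
    query <- c(universe[seq_len(k)], universe[(K + 1):(K + n - k)])
    res <- hypergeom_enrich(query, gsc)
    expect_lte(res$p_value, prev)
    prev <- res$p_value
    fisher <- fisher.test(matrix(c(k, n - k, K - k, N - K - n + k), 2),
                          alternative = "greater")
    expect_equal(res$p_value, fisher$p.value, tolerance = 1e-12)
  }
})

test_that("genes outside the universe are dropped with a report", {
  gsc <- gene_set_collection(list(S = letters[1:4]),
                             universe = letters[1:8])
  expect_message(res <- hypergeom_enrich(c("a", "b", "zz"), gsc),
                 "1 query gene")
  expect_equal(res$n, 2L)
  expect_error(hypergeom_enrich("a", gene_set_collection(
    list(), universe = character(0))), "empty universe")
})

test_that("per-timepoint enrichment mirrors the pathway-table layout", {
  # all 8 h genes belong to one set; 1 h has no significant genes
  p <- matrix(1, 20, 3, dimnames = list(sprintf("g%02d", 1:20),
                                        c("1", "8", "12")))
  p[1:6, "8"] <- 1e-6
  p[15, "12"] <- 1e-6
  tbl <- table_from_p(p, alpha = 1e-4)
  gsc <- gene_set_collection(list(hot = sprintf("g%02d", 1:6),
                                  cold = sprintf("g%02d", 10:14)),
                             universe = rownames(p))
  res <- enrich_by_timepoint(tbl, gsc, threshold = 0.01)
  expect_named(res, c("any", "1", "8", "12"))
  expect_equal(nrow(res[["1"]]), 0L)                    # n = 0 column
  hot8 <- res[["8"]][res[["8"]]$set == "hot", ]
  expect_true(hot8$passes)
  expect_equal(hot8$k, 6L)
  expect_false("hot" %in% res[["12"]]$set)              # no overlap at 12 h

  # with a single active timepoint the union query gives the identical p
  p1 <- matrix(1, 20, 2, dimnames = list(rownames(p), c("4", "8")))
  p1[1:6, "8"] <- 1e-6
  res1 <- enrich_by_timepoint(table_from_p(p1), gsc)
  expect_equal(res1[["any"]]$p_value, res1[["8"]]$p_value)

  out <- enrichment_table(res, threshold = 0.01)
  expect_true("hot" %in% out$pathway)
  expect_true(all(out[out$pathway == "hot", grepl("^12",
                                                  names(out))] == "-"))
})
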