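test_that("pooled-variance t-test matches the closed form and is symmetric", {
  fix <- tiny_expression(matrix(c(10, 11, 12, 13, 14, 15), nrow = 1))
  r <- ttest_vs_baseline(fix$m, fix$design, 4)
  # |t| = 3/sqrt(2/3) on 4 df; the sign follows the log-ratio (t - baseline)
  expect_equal(abs(r$t_statistic), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-3 / sqrt(2 / 3), df = 4),
               tolerance = 1e-12)
  expect_equal(r$p_value, 0.0213, tolerance = 1e-3)
  expect_equal(r$log_ratio, 3)

  # identical groups: t = 0, p = 1
  fix0 <- tiny_expression(matrix(c(5, 6, 7, 5, 6, 7), nrow = 1))
  r0 <- ttest_vs_baseline(fix0$m, fix0$design, 4)
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)

  # swapping the group labels negates t, leaves p unchanged
  swapped <- tiny_expression(matrix(c(13, 14, 15, 10, 11, 12), nrow = 1))
  rs <- ttest_vs_baseline(swapped$m, swapped$design, 4)
  expect_equal(rs$t_statistic, -r$t_statistic, tolerance = 1e-12)
  expect_equal(rs$p_value, r$p_value, tolerance = 1e-12)
})

test_that("t-test p-values agree with stats::t.test on random draws", {
  set.seed(123)
  for (i in 1:100) {
    v <- c(rnorm(3, 8, 1), rnorm(3, 8 + runif(1, -2, 2), 1))
    fix <- tiny_expression(matrix(v, nrow = 1))
    r <- ttest_vs_baseline(fix$m, fix$design, 4)
    ref <- t.test(v[4:6], v[1:3], var.equal = TRUE)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(r$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("zero pooled variance with unequal means hits the p = 0 policy", {
  fix <- tiny_expression(matrix(c(5, 5, 5, 7, 7, 7), nrow = 1))
  expect_warning(r <- ttest_vs_baseline(fix$m, fix$design, 4),
                 "zero pooled variance")
  expect_equal(r$p_value, 0)
  expect_equal(attr(r, "n_zero_variance"), 1L)
  # a variance floor defuses the degenerate case
  r2 <- ttest_vs_baseline(fix$m, fix$design, 4, var_floor = 0.01)
  expect_true(is.finite(r2$t_statistic) && r2$p_value > 0)
})

test_that("responsive selection uses a strict threshold and earliest onset", {
  p <- cbind(`1` = c(0.5, 0.9, 0.2), `4` = c(2e-5, 1e-4, 0.3),
             `8` = c(0.3, 0.5, 0.9), `12` = c(1e-6, 0.2, 0.99))
  rownames(p) <- c("gA", "gB", "gC")
  tbl <- table_from_p(p)
  g <- tbl$genes
  expect_true(g$responsive[g$gene == "gA"])
  expect_equal(g$first_time[g$gene == "gA"], 4)
  expect_equal(g$n_significant_timepoints[g$gene == "gA"], 2L)
  # p exactly 1e-4 is NOT significant (strict <)
  expect_false(g$responsive[g$gene == "gB"])
  expect_false(g$responsive[g$gene == "gC"])
  # all p above alpha: zero responsive
  expect_equal(sum(table_from_p(p, alpha = 1e-9)$genes$responsive), 0L)
})

test_that("direction comes from the minimal-p timepoint, earlier on ties", {
  p <- cbind(`4` = c(0.5, 1e-5), `8` = c(1e-6, 1e-5), `12` = c(0.2, 0.9))
  lr <- cbind(`4` = c(0.4, -2.0), `8` = c(1.3, 3.0), `12` = c(-9, 9))
  rownames(p) <- rownames(lr) <- c("gUp", "gTie")
  g <- table_from_p(p, lr)$genes
  expect_equal(g$direction[g$gene == "gUp"], "up")      # lr +1.3 at min-p 8h
  # tie between 4h and 8h: the earlier (4 h) log-ratio (-2.0) decides
  expect_equal(g$direction[g$gene == "gTie"], "down")

  # exact zero log-ratio at the deciding timepoint: down with a warning
  p0 <- cbind(`4` = 1e-6); lr0 <- cbind(`4` = 0)
  rownames(p0) <- rownames(lr0) <- "gZero"
  expect_warning(g0 <- table_from_p(p0, lr0)$genes, "convention")
  expect_equal(g0$direction, "down")
})

test_that("dynamics bookkeeping matches hand enumeration", {
  # 3 genes significant only at 8 h; 1 gene at 4 h and 8 h
  p <- cbind(`4` = c(1, 1, 1, 1e-6), `8` = rep(1e-6, 4), `12` = rep(1, 4))
  rownames(p) <- paste0("g", 1:4)
  dyn <- summarize_dynamics(table_from_p(p))
  per <- dyn$per_timepoint
  expect_equal(per$n_significant[per$timepoint_h == 8], 4L)
  expect_equal(per$n_new[per$timepoint_h == 8], 3L)
  expect_equal(per$n_repeat[per$timepoint_h == 8], 1L)
  expect_equal(per$repeat_fraction[per$timepoint_h == 8], 0.25)
  expect_equal(dyn$n_one_timepoint, 3L)
  expect_equal(dyn$n_two_timepoints, 1L)
  expect_equal(dyn$n_responsive, 4L)

  # no responsive genes: all zero
  dyn0 <- summarize_dynamics(table_from_p(p, alpha = 1e-9))
  expect_equal(dyn0$n_responsive, 0L)
  expect_true(all(dyn0$per_timepoint$n_significant == 0L))
})

test_that("dynamics conservation identities hold on random fixtures", {
  set.seed(99)
  for (i in 1:25) {
    p <- matrix(runif(60)^4, 12, 5,
                dimnames = list(sprintf("g%02d", 1:12), c(1, 4, 8, 12, 24)))
    tbl <- table_from_p(p, alpha = 0.05)
    dyn <- summarize_dynamics(tbl)
    per <- dyn$per_timepoint
    expect_equal(per$n_significant, per$n_new + per$n_repeat)
    expect_equal(sum(per$n_new), dyn$n_responsive)
    expect_equal(dyn$n_one_timepoint + dyn$n_two_timepoints +
                   dyn$n_more_than_two, dyn$n_responsive)
    expect_equal(dyn$n_up + dyn$n_down, dyn$n_responsive)
    # first significant time bounds every significant time
    g <- tbl$genes[tbl$genes$responsive, ]
    for (k in seq_len(nrow(g))) {
      tsig <- tbl$timepoints[tbl$significant[g$gene[k], ]]
      expect_true(all(g$first_time[k] <= tsig))
    }
  }
})

test_that("relative profiles are baseline-anchored and shift-invariant", {
  set.seed(5)
  sim <- simulate_expression(simulation_config(
    n_genes = 10, fraction_responsive = 0, rng_seed = 5))
  m <- to_log2(sim$values, offset = 0)
  prof <- relative_profiles(m, sim$design)
  expect_equal(unname(prof[, "0"]), rep(0, 10))

  # +1 log2 at 8 h only shows up as +1 at 8 h
  m2 <- unclass(m)
  s8 <- sim$design$sample_id[sim$design$timepoint_h == 8]
  m2["g00003", s8] <- m2["g00003", s8] + 1
  prof2 <- relative_profiles(expression_matrix(m2, "log2"), sim$design,
                             "g00003")
  expect_equal(prof2[1, "8"] - prof[["g00003", "8"]], 1, tolerance = 1e-12)

  # adding a constant to every sample of a gene leaves its profile alone
  m3 <- unclass(m); m3["g00004", ] <- m3["g00004", ] + 7
  expect_equal(relative_profiles(expression_matrix(m3, "log2"),
                                 sim$design, "g00004"),
               prof["g00004", , drop = FALSE], tolerance = 1e-12)

  expect_error(relative_profiles(m, sim$design, "nope"), "unknown gene")
})
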