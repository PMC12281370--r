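test_that("KM steps and median match the hand product-limit computation", {
  km <- km_estimate(c(2, 4, 6, 8), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 4)   # smallest time with S <= 0.5
  all_cens <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))
  expect_true(is.na(all_cens$median))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(21)
  t <- rexp(300, 0.2)
  km <- km_estimate(t, rep(1, 300))
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("KM median recovers the analytic exponential median", {
  set.seed(42)
  km <- km_estimate(rexp(1000, 0.1), rep(1, 1000))
  expect_lt(abs(km$median - log(2) / 0.1), 0.15 * log(2) / 0.1)
})

test_that("log-rank is zero for identical groups, symmetric and non-negative", {
  t <- c(2, 3, 5, 8, 13, 2, 3, 5, 8, 13)
  e <- rep(1, 10)
  g <- rep(c("a", "b"), each = 5)
  lr <- logrank(t, e, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-9)
  set.seed(6)
  t2 <- rexp(40, 0.1); e2 <- rbinom(40, 1, 0.8)
  g2 <- rep(c("a", "b"), 20)
  lr_ab <- logrank(t2, e2, g2)
  lr_ba <- logrank(t2, e2, ifelse(g2 == "a", "b", "a"))
  expect_equal(lr_ab$statistic, lr_ba$statistic)
  expect_gte(lr_ab$statistic, 0)
  expect_equal(logrank(c(1, 2), c(0, 0), c("a", "b"))$statistic, 0)
})

test_that("strongly separated hazards are detected with high power", {
  set.seed(99)
  reject <- replicate(50, {
    t <- c(rexp(200, 0.4), rexp(200, 0.1))
    logrank(t, rep(1, 400), rep(c("a", "b"), each = 200))$p < 0.001
  })
  expect_gte(mean(reject), 0.95)
})

test_that("group comparisons dispatch to the appropriate test", {
  same <- suppressWarnings(group_compare(1:10, 1:10, "continuous"))
  expect_equal(same$method, "Wilcoxon-Mann-Whitney")
  expect_gt(same$p, 0.95)
  # completely separated groups reach the exact two-sided minimum for n=10,10
  sep <- stats::wilcox.test(1:10, 101:110, exact = TRUE)
  expect_equal(group_compare(as.numeric(1:10), as.numeric(101:110),
                             "continuous")$p,
               2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(sep$p.value, 2 / choose(20, 10), tolerance = 1e-9)
  # 30/31 vs 4/19 concurrent-Th1: Fisher, p < 0.001
  a <- rep(c(TRUE, FALSE), c(30, 1))
  b <- rep(c(TRUE, FALSE), c(4, 15))
  cat_cmp <- group_compare(a, b, "categorical")
  expect_equal(cat_cmp$method, "Fisher exact")
  expect_equal(unname(cat_cmp$proportions), c(30 / 31, 4 / 19),
               tolerance = 1e-12)
  expect_lt(cat_cmp$p, 0.001)
  big <- group_compare(rep(c(TRUE, FALSE), c(40, 40)),
                       rep(c(TRUE, FALSE), c(20, 60)), "categorical")
  expect_equal(big$method, "Chi-square")
})

test_that("triad status is the strict conjunction of the three calls", {
  expect_true(triad_status("polyF_triple", TRUE, TRUE))
  expect_false(triad_status("polyF_triple", TRUE, FALSE))
  expect_false(triad_status("polyF_double", TRUE, TRUE))
  expect_true(is.na(triad_status("polyF_triple", NA, TRUE)))
  v <- triad_status(c("polyF_triple", "singleF"), c(TRUE, TRUE),
                    c(TRUE, TRUE))
  expect_equal(v, c(TRUE, FALSE))
})

test_that("clustering recovers perfectly separated blocks and rejects degenerate input", {
  feats <- rbind(matrix(rep(c(0, 0, 0), 8), ncol = 3, byrow = TRUE),
                 matrix(rep(c(10, 10, 10), 7), ncol = 3, byrow = TRUE))
  feats <- feats + matrix(rnorm(45, sd = 0.01), ncol = 3)
  rownames(feats) <- sprintf("P%02d", 1:15)
  g <- immune_group_clustering(feats, k = 2, seed = 1)
  expect_equal(length(unique(g$cluster[1:8])), 1)
  expect_equal(length(unique(g$cluster[9:15])), 1)
  expect_false(g$cluster[1] == g$cluster[9])
  expect_error(immune_group_clustering(feats[1, , drop = FALSE], k = 2),
               "two complete-case")
  feats2 <- cbind(feats, const = 1)
  expect_warning(immune_group_clustering(feats2, k = 2, seed = 1),
                 "constant")
})

test_that("clustering is deterministic given the seed and co-clusters triad-like patients", {
  set.seed(1234)
  n_triad <- 7; n_rest <- 33
  # triad patients form a tight distant block; the rest are heterogeneous
  # (spanning non/weak/moderate responders), as in a real cohort
  mk_feat <- function() {
    rbind(cbind(rnorm(n_triad, 150, 5), rnorm(n_triad, 0.5, 0.02),
                rnorm(n_triad, 4000, 150), rnorm(n_triad, 3, 0.2)),
          cbind(runif(n_rest, 0, 60), runif(n_rest, 0, 0.1),
                runif(n_rest, 0, 800), runif(n_rest, 0, 1)))
  }
  co <- replicate(20, {
    f <- mk_feat()
    rownames(f) <- sprintf("P%02d", seq_len(nrow(f)))
    g <- immune_group_clustering(f, k = 4, seed = 11)
    length(unique(g$cluster[1:n_triad])) == 1
  })
  expect_gte(mean(co), 0.95)
  f <- mk_feat(); rownames(f) <- sprintf("P%02d", seq_len(nrow(f)))
  g1 <- immune_group_clustering(f, k = 3, seed = 5)
  g2 <- immune_group_clustering(f, k = 3, seed = 5)
  expect_identical(g1$cluster, g2$cluster)
})
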