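test_that("kruskal_wallis matches hand-computed rank sums", {
  # groups {1,2},{3,4},{5,6}: rank sums 3, 7, 11 -> H = 12/(6*7) * sum(R^2/2) - 21
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
  h_hand <- 12 / (6 * 7) * (3^2 / 2 + 7^2 / 2 + 11^2 / 2) - 3 * 7
  expect_equal(kw$statistic, h_hand, tolerance = 1e-10)

  # identical groups: H ~ 0, p ~ 1
  kw0 <- kruskal_wallis(rep(c(3, 1, 4), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(kw0$statistic, 1e-10)
  expect_gt(kw0$p_value, 0.99)

  expect_error(kruskal_wallis(1:4, rep(c("a", "b"), 2)), "mann_whitney")
})

test_that("kruskal_wallis p-values are uniform under label permutation", {
  set.seed(131)
  x <- rnorm(18)
  ps <- replicate(400, {
    kruskal_wallis(x, sample(rep(c("a", "b", "c"), each = 6)))$p_value
  })
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.06)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.04)
})

test_that("mann_whitney: exact enumeration and identity cases", {
  # a = {1,2,3}, b = {4,5,6}: U = 0, exact two-sided p = 2/20 = 0.1
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_true(mw$exact)
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)

  # identical multisets: U = n^2/2, p in the 1 region
  mw2 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(mw2$statistic, 8)
  expect_gt(mw2$p_value, 0.99)

  # oracle: U equals the all-pairs count (ties scoring 1/2)
  set.seed(132)
  for (r in 1:10) {
    a <- sample(1:8, 15, replace = TRUE)
    b <- sample(2:9, 12, replace = TRUE)
    u_oracle <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(mann_whitney(a, b)$statistic, u_oracle)
  }
})

test_that("fold_change reproduces reported rounding and reciprocity", {
  expect_equal(as.numeric(fold_change(1.41, 0.33)), 4.3)
  expect_equal(as.numeric(fold_change(1.04, 0.47)), 2.2)
  expect_equal(as.numeric(fold_change(3, 3)), 1.0)
  expect_equal(as.numeric(fold_change(0.92, 2.32, percent = TRUE)), 40)
  expect_warning(fc0 <- fold_change(1, 0), "zero denominator")
  expect_true(is.na(fc0))
  # reciprocity before rounding
  f1 <- fold_change(c(2, 4, 9), c(1, 2, 3))
  f2 <- fold_change(c(1, 2, 3), c(2, 4, 9))
  expect_equal(attr(f1, "raw") * attr(f2, "raw"), 1)
})

test_that("ROC AUC equals Mann-Whitney U/(n1 n2) on random fixtures", {
  set.seed(141)
  for (r in 1:20) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    v <- c(rnorm(n1, 0.5), rnorm(n0))
    if (r %% 2 == 0) v <- round(v)   # force ties half the time
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    roc <- roc_curve(v, lab)
    u <- sum(outer(v[lab], v[!lab], ">")) + 0.5 * sum(outer(v[lab], v[!lab], "=="))
    expect_equal(roc$auc, u / (n1 * n0))
    expect_equal(roc$p_value, mann_whitney(v[lab], v[!lab])$p_value)
  }
})

test_that("ROC handles separation and permuted labels as expected", {
  expect_equal(roc_curve(c(1, 2, 5, 6), c(FALSE, FALSE, TRUE, TRUE))$auc, 1.0)
  set.seed(142)
  v <- rnorm(300)
  auc0 <- roc_curve(v, sample(rep(c(TRUE, FALSE), 150)))$auc
  expect_equal(auc0, 0.5, tolerance = 0.1)
  # anti-discriminating marker is not flipped
  expect_equal(roc_curve(c(5, 6, 1, 2), c(FALSE, FALSE, TRUE, TRUE))$auc, 0)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("optimal_cutpoint maximizes sens+spec over an exhaustive scan", {
  # separated groups {1,2} vs {5,6}: returns observed value 5, sens = spec = 1
  oc <- optimal_cutpoint(c(1, 2, 5, 6), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(oc$cutoff, 5)
  expect_equal(oc$sensitivity, 1)
  expect_equal(oc$specificity, 1)

  set.seed(143)
  for (r in 1:10) {
    v <- round(rnorm(40), 1)
    lab <- runif(40) < 0.4
    if (!any(lab) || all(lab)) next
    oc <- optimal_cutpoint(v, lab)
    # self-consistency at the returned cutoff
    pred <- v >= oc$cutoff
    expect_equal(mean(pred[lab]), oc$sensitivity)
    expect_equal(mean(!pred[!lab]), oc$specificity)
    # no other observed threshold does better
    best <- max(vapply(unique(v), function(cc) {
      p <- v >= cc
      mean(p[lab]) + mean(!p[!lab])
    }, numeric(1)))
    expect_equal(oc$sensitivity + oc$specificity, best)
  }
})

test_that("spearman_cor matches the hand rank formula and is monotone-invariant", {
  # {(1,2),(2,1),(3,4),(4,3),(5,5)}: d^2 sums to 4 -> rho = 1 - 24/120 = 0.8
  sc <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(sc$rho, 0.8)

  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)

  set.seed(144)
  x <- rnorm(30); y <- rnorm(30)
  s0 <- spearman_cor(x, y)
  s1 <- spearman_cor(exp(x), y)            # strictly monotone transform
  s2 <- spearman_cor(x, 3 * y - 7)
  expect_equal(s0$rho, s1$rho)
  expect_equal(s0$p_value, s2$p_value)

  expect_warning(sc_const <- spearman_cor(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(sc_const$rho))
  expect_warning(spearman_cor(1:3, 3:1), "pairs")
})
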