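test_that("size_factors: identity, doubling, and definition oracle", {
  cm <- random_counts(n_mirna = 40, n_samples = 2, seed = 71)
  eq <- cbind(a = cm[, 1], b = cm[, 1])
  expect_equal(unname(size_factors(eq)), c(1, 1))

  dbl <- cbind(a = cm[, 1] + 1L, b = 2L * (cm[, 1] + 1L))
  sf <- size_factors(dbl)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # brute-force per-definition computation
  cm2 <- random_counts(n_mirna = 30, n_samples = 6, seed = 72) + 1L
  sf2 <- size_factors(cm2)
  loggm <- rowMeans(log(cm2))
  oracle <- apply(cm2, 2, function(col) median(exp(log(col) - loggm)))
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(sf2, oracle)

  # all-zero-containing rows only: falls back to totals
  cm3 <- matrix(c(0L, 5L, 8L, 0L), 2, 2)
  expect_warning(sf3 <- size_factors(cm3), "falling back")
  expect_equal(exp(mean(log(sf3))), 1)
})

test_that("dispersion estimation recovers simulated alpha", {
  set.seed(81)
  n <- 200
  # Poisson counts: alpha at floor
  y_pois <- matrix(rpois(50 * n, 40), 50, n)
  d_pois <- estimate_dispersion(y_pois, rep(1, n))
  expect_lt(median(d_pois$dispersion), 0.01)

  # NB alpha = 0.5
  y_nb <- matrix(rnbinom(50 * n, mu = 60, size = 2), 50, n)
  d_nb <- estimate_dispersion(y_nb, rep(1, n))
  expect_gt(median(d_nb$dispersion), 0.35)
  expect_lt(median(d_nb$dispersion), 0.65)

  # constant counts: zero variance, alpha at floor
  y_c <- matrix(7, 3, 10)
  d_c <- estimate_dispersion(y_c, rep(1, 10), floor = 1e-8)
  expect_equal(d_c$dispersion, rep(1e-8, 3))

  expect_error(estimate_dispersion(y_c, rep(1, 10), groups = c("a", rep("b", 9))),
               "a")
})

test_that("nb_wald_test recovers an exact two-fold difference", {
  # deterministic counts: group A exactly 2x group B, near-zero dispersion
  base <- c(100L, 40L, 250L, 80L)
  y <- cbind(a1 = 2L * base, a2 = 2L * base, b1 = base, b2 = base)
  rownames(y) <- paste0("m", 1:4)
  de <- nb_wald_test(y, c("A", "A", "B", "B"), c("A", "B"),
                     sf = setNames(rep(1, 4), colnames(y)))
  expect_equal(de$log2fc, rep(1, 4), tolerance = 1e-4)
  expect_true(all(de$p_adj >= de$p_value, na.rm = TRUE))
})

test_that("swapping the contrast negates log2fc and keeps p-values", {
  co <- simulate_cohort(small_sim(seed = 91))
  d2 <- co$meta$timepoint == "D2"
  de1 <- nb_wald_test(co$counts[, d2], co$meta$group[d2], c("TBI", "sham"))
  de2 <- nb_wald_test(co$counts[, d2], co$meta$group[d2], c("sham", "TBI"))
  expect_equal(de1$log2fc, -de2$log2fc, tolerance = 1e-6)
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-6)

  # BH monotonicity: p_adj is non-decreasing along increasing p
  ok <- !is.na(de1$p_value)
  o <- order(de1$p_value[ok])
  expect_true(all(diff(de1$p_adj[ok][o]) >= -1e-12))
  # planted effects are detected
  hits <- de1$mirna_id[!is.na(de1$p_adj) & de1$p_adj < 0.05 & de1$log2fc > 0]
  expect_gt(mean(co$truth$responsive %in% hits), 0.6)
})

test_that("all-zero miRNAs are excluded and recorded", {
  y <- random_counts(n_mirna = 20, n_samples = 8, seed = 95)
  y[3, ] <- 0L
  y[17, ] <- 0L
  de <- nb_wald_test(y, rep(c("A", "B"), each = 4), c("A", "B"))
  expect_setequal(attr(de, "excluded"), c("mir003", "mir017"))
  expect_equal(nrow(de), 18L)
  expect_error(nb_wald_test(y, rep(c("A", "B"), c(7, 1)), c("A", "B")),
               ">= 2 samples")
})

test_that("NB Wald log2fc agrees with DESeq2 on a common fixture", {
  # independent cross-check of effect-size estimation (not a stand-in for
  # our implementation: shrinkage-free settings, large clean effects)
  set.seed(97)
  n <- 10
  mu <- rep(c(200, 50, 400, 120, 800), 4)
  fc <- rep(c(1, 4, 1, 0.25, 1), 4)
  y <- t(vapply(seq_len(20), function(i) {
    c(rnbinom(n, mu = mu[i] * fc[i], size = 10), rnbinom(n, mu = mu[i], size = 10))
  }, numeric(2 * n)))
  dimnames(y) <- list(paste0("m", 1:20), paste0("s", 1:(2 * n)))
  grp <- rep(c("TBI", "sham"), each = n)
  de <- nb_wald_test(y, grp, c("TBI", "sham"))

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = y,
      colData = data.frame(condition = factor(grp, levels = c("sham", "TBI"))),
      design = ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("condition", "TBI", "sham"))
  })
  expect_equal(de$log2fc, res$log2FoldChange, tolerance = 0.15)
  # significance calls agree for the strong planted effects
  expect_equal(de$p_adj < 0.05, res$padj < 0.05)
})
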