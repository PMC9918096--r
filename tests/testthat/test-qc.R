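test_that("cpm_normalize matches hand arithmetic and is scale invariant", {
  m <- matrix(c(1, 3, 6), ncol = 1, dimnames = list(paste0("m", 1:3), "s1"))
  expect_equal(as.numeric(cpm_normalize(m)), c(1e5, 3e5, 6e5))

  eq <- matrix(7, nrow = 4, ncol = 2,
               dimnames = list(paste0("m", 1:4), c("a", "b")))
  expect_true(all(cpm_normalize(eq) == 1e6 / 4))

  cm <- random_counts(seed = 3)
  out <- cpm_normalize(cm)
  expect_equal(unname(colSums(out)), rep(1e6, ncol(cm)))
  # multiplying a sample's counts by k leaves its CPM column unchanged
  cm2 <- cm
  cm2[, 4] <- cm2[, 4] * 5L
  expect_equal(cpm_normalize(cm2)[, 4], out[, 4])

  zm <- cm
  zm[, "s02"] <- 0L
  expect_error(cpm_normalize(zm), "s02")
})

test_that("hemolysis_qc applies the strict A414 < 0.25 rule", {
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     a414 = c(0.24, 0.25, 0.10, 0.10),
                     plasma_volume_ok = c(TRUE, TRUE, FALSE, TRUE))
  qc <- hemolysis_qc(meta)
  expect_true(qc$qualified[["a"]])   # 0.24 passes: strict inequality
  expect_false(qc$qualified[["b"]])  # 0.25 is hemolyzed
  expect_false(qc$qualified[["c"]])  # insufficient volume fails
  expect_true(qc$qualified[["d"]])
  expect_equal(qc$n_qualified, 2L)
  expect_equal(qc$percent, 50L)
})

test_that("hemolysis_qc percentage equals round(100 * qualified/total)", {
  set.seed(11)
  for (r in 1:10) {
    n <- sample(20:200, 1)
    meta <- data.frame(sample_id = seq_len(n),
                       a414 = runif(n, 0.05, 0.40),
                       plasma_volume_ok = runif(n) < 0.9)
    qc <- hemolysis_qc(meta)
    expect_equal(qc$percent,
                 as.integer(floor(100 * qc$n_qualified / n + 0.5)))
  }
})

test_that("detection_sets recovers a planted detection pattern", {
  # 3 groups x 4 samples; plant miRNAs detected in known group combinations
  grp <- rep(c("naive", "sham", "TBI"), each = 4)
  m <- matrix(0L, 7, 12,
              dimnames = list(c("all3", "ns", "nt", "st", "n_only",
                                "s_only", "t_only"),
                              paste0("s", 1:12)))
  m["all3", c(1, 5, 9)] <- 1L
  m["ns", c(2, 6)] <- 3L
  m["nt", c(3, 10)] <- 1L
  m["st", c(7, 11)] <- 2L
  m["n_only", 4] <- 1L
  m["s_only", 8] <- 1L
  m["t_only", 12] <- 9L
  ds <- detection_sets(m, grp)
  expect_equal(unname(ds$sizes), c(4L, 4L, 4L))
  expect_equal(sort(ds$intersections[["naive&sham&TBI"]]), "all3")
  expect_equal(sort(ds$intersections[["naive&sham"]]), c("all3", "ns"))
  expect_equal(sort(ds$exclusive[["TBI"]]), "t_only")
  expect_equal(ds$n_detected, 7L)

  # two identical groups: intersection equals each group's set
  g2 <- rep(c("A", "B"), each = 2)
  m2 <- cbind(m[, 1:2], m[, 1:2])
  ds2 <- detection_sets(m2, g2)
  expect_setequal(ds2$intersections[["A&B"]], ds2$sets$A)
})

test_that("prevalence_filter matches a brute-force row scan and is monotone", {
  cm <- random_counts(n_mirna = 60, n_samples = 10, seed = 5,
                      lambda_range = c(0.2, 50))
  out <- prevalence_filter(cm, min_count = 1, min_fraction = 0.8)
  oracle <- rownames(cm)[vapply(seq_len(nrow(cm)), function(i) {
    sum(cm[i, ] >= 1) >= ceiling(0.8 * ncol(cm))
  }, logical(1))]
  expect_identical(rownames(out), oracle)

  # 7/10 samples at min_fraction 0.8 is dropped (7 < 8)
  cm2 <- matrix(c(rep(1L, 7), 0L, 0L, 0L), nrow = 1,
                dimnames = list("m7", paste0("s", 1:10)))
  expect_equal(nrow(prevalence_filter(cm2)), 0L)

  # raising min_fraction never adds miRNAs
  prev <- rownames(prevalence_filter(cm, min_fraction = 0.2))
  for (f in c(0.4, 0.6, 0.8, 1.0)) {
    cur <- rownames(prevalence_filter(cm, min_fraction = f))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("pca_summary: duplicates, rank-1 structure, eigenvalue oracle", {
  cm <- random_counts(n_mirna = 30, n_samples = 5, seed = 7)
  cpm <- cpm_normalize(cm)
  dup <- cbind(cpm, cpm)
  colnames(dup) <- paste0("s", seq_len(ncol(dup)))
  p <- pca_summary(dup)
  expect_equal(p$scores[1:5, ], p$scores[6:10, ], ignore_attr = TRUE)

  # rank-1 matrix: PC1 explains ~100%
  u <- exp(rnorm(20)); v <- exp(rnorm(6))
  r1 <- outer(u, v)
  p1 <- pca_summary(r1, log_transform = FALSE)
  expect_gt(p1$percent_var[1], 99.9)

  # eigen-decomposition oracle on a small matrix
  set.seed(8)
  x <- matrix(rnorm(12), 4, 3)      # 3 samples
  ps <- pca_summary(x, log_transform = FALSE)
  ev <- eigen(cov(t(x)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ps$sdev^2, decreasing = TRUE),
               sort(ev, decreasing = TRUE)[seq_along(ps$sdev)],
               tolerance = 1e-8)

  # constant matrix handled without crash
  pc <- pca_summary(matrix(5, 10, 4), log_transform = FALSE)
  expect_true(all(pc$percent_var == 0))

  expect_true(all(diff(p$percent_var) <= 1e-8))
  expect_lte(sum(p$percent_var), 100 + 1e-8)
})
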