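test_that("simulate_cohort is deterministic and validates its inputs", {
  co1 <- simulate_cohort(small_sim(seed = 11))
  co2 <- simulate_cohort(small_sim(seed = 11))
  expect_identical(co1, co2)
  co3 <- simulate_cohort(small_sim(seed = 12))
  expect_false(identical(co1$counts, co3$counts))

  expect_error(sim_config(epilepsy_rate = 1.2), "epilepsy_rate")
  expect_error(sim_config(lib_size_mean = 0), "lib_size_mean")
  expect_error(sim_config(nb_dispersion = 0))

  # identifiers cross-reference
  expect_setequal(colnames(co1$counts), co1$meta$sample_id)
  expect_true(all(co1$ddpcr$sample_id %in% co1$meta$sample_id))
  expect_setequal(names(co1$truth$epilepsy), unique(co1$meta$animal_id))
})

test_that("null injury effect gives equal group mean CPMs", {
  cfg <- sim_config(n_naive = 0, n_sham = 25, n_tbi = 25, n_mirna = 60,
                    n_injury_responsive = 10, injury_log2fc = 0,
                    seed = 21)
  co <- simulate_cohort(cfg)
  d2 <- co$meta$timepoint == "D2"
  cpm <- cpm_normalize(co$counts[, d2])
  grp <- co$meta$group[d2]
  resp <- co$truth$responsive
  m_tbi <- rowMeans(cpm[resp, grp == "TBI"])
  m_sham <- rowMeans(cpm[resp, grp == "sham"])
  # log-ratio of group means near 0 within sampling error
  expect_lt(max(abs(log2((m_tbi + 1) / (m_sham + 1)))), 0.5)
})

test_that("epilepsy labels follow the configured prevalence", {
  # expected 21 TBI+ of 90 at rate 21/90; average over replicate cohorts
  n_epi <- vapply(1:20, function(s) {
    co <- simulate_cohort(sim_config(n_naive = 0, n_sham = 2, n_tbi = 90,
                                     n_mirna = 5, n_injury_responsive = 0,
                                     seed = 100 + s))
    sum(co$truth$epilepsy)
  }, numeric(1))
  expect_equal(mean(n_epi), 21, tolerance = 0.1)  # binomial mean 21, se ~ 0.9
})

test_that("droplet readout follows Poisson occupancy statistics", {
  expect_equal(simulate_droplet_readout(0, 1000, 0.001)$positives, 0L)
  expect_error(simulate_droplet_readout(-1, 1000, 0.001), ">= 0")

  # lambda = ln 2 gives expected positive fraction 1/2
  set.seed(31)
  frac <- mean(replicate(50, {
    r <- simulate_droplet_readout(log(2), 2000, 1)
    r$positives / r$total
  }))
  expect_equal(frac, 0.5, tolerance = 0.01)

  # closed-form binomial mean: 20000 * (1 - exp(-0.085)) = 1629.9
  set.seed(32)
  pos <- replicate(40, simulate_droplet_readout(100, 20000, 0.00085)$positives)
  expect_equal(mean(pos), 20000 * (1 - exp(-0.085)), tolerance = 0.01)
})

test_that("simulated T2 volumes have the designed lesion structure", {
  expect_error(simulate_t2_volume(c(0, 5, 5), 0.1), "positive")
  expect_error(simulate_t2_volume(c(5, 5, 5), 1.5), "lesion_fraction")

  v0 <- simulate_t2_volume(c(20, 20, 10), 0, seed = 41)
  out_band <- mean(v0$t2 < 45 | v0$t2 > 55)
  expect_lt(abs(out_band - 0.05), 0.01)  # Gaussian tails 2.5% + 2.5%

  v <- simulate_t2_volume(c(20, 20, 10), 0.2, lesion_shift_ms = 30, seed = 42)
  expect_gte(mean(v$t2 < 45 | v$t2 > 55), 0.2)
  expect_equal(mean(v$lesion), 0.2, tolerance = 0.001)
  # lesion core is contiguous around the center
  expect_true(v$lesion[10, 10, 5])

  v2 <- simulate_t2_volume(c(20, 20, 10), 0.2, lesion_shift_ms = 30, seed = 42)
  expect_identical(v, v2)
})

test_that("simulated counts match the configured NB mean-variance relation", {
  cfg <- sim_config(n_naive = 0, n_sham = 150, n_tbi = 0, n_mirna = 40,
                    n_injury_responsive = 0, nb_dispersion = 0.4,
                    lib_size_cv = 0, seed = 51)
  co <- simulate_cohort(cfg)
  d2 <- co$meta$timepoint == "D2"
  y <- co$counts[, d2]
  mu <- rowMeans(y)
  v <- apply(y, 1, var)
  keep <- mu > 50     # moment estimates are stable for abundant miRNAs
  alpha_hat <- (v[keep] - mu[keep]) / mu[keep]^2
  expect_equal(median(alpha_hat), 0.4, tolerance = 0.15)
})

test_that("severity couples miRNA levels to lesion volume but not epilepsy", {
  cfg <- sim_config(n_naive = 0, n_sham = 8, n_tbi = 60, n_mirna = 60,
                    n_injury_responsive = 10,
                    injury_log2fc = 2, lesion_coupling = 0.15,
                    epilepsy_coupling = 0, seed = 61)
  co <- simulate_cohort(cfg)
  d2 <- co$meta$timepoint == "D2" & co$meta$group == "TBI"
  cpm <- cpm_normalize(co$counts)[, d2]
  sev <- co$truth$severity[co$meta$animal_id[d2]]
  band <- normal_t2_band(Filter(function(v) startsWith(v$sample_id, "SHM"), co$t2))
  tbi_d2 <- Filter(function(v) startsWith(v$sample_id, "TBI") && v$timepoint == "D2",
                   co$t2)
  vol <- vapply(tbi_d2, function(v) lesion_volume(v, band)$volume_mm3, numeric(1))
  vol <- vol[match(co$meta$animal_id[d2], sub("_D2$", "", names(vol)))]

  resp <- co$truth$responsive
  nonresp <- setdiff(rownames(cpm), resp)[1:10]
  rho_resp <- vapply(resp, function(m) spearman_cor(cpm[m, ], vol)$rho, numeric(1))
  rho_non <- vapply(nonresp, function(m) spearman_cor(cpm[m, ], vol)$rho, numeric(1))
  expect_gt(mean(rho_resp), 0.5)   # responsive miRNAs track lesion volume
  # background miRNAs show no positive coupling (CPM closure can push them
  # slightly negative when responsive miRNAs inflate the library)
  expect_lt(mean(rho_non), 0.1)

  # epilepsy decoupled: responsive-miRNA AUC for the outcome stays at chance
  epi <- co$meta$epilepsy[d2]
  if (sum(epi) >= 3 && sum(!epi) >= 3) {
    aucs <- vapply(resp, function(m) auc_rank <- roc_curve(cpm[m, ], epi)$auc,
                   numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.2)
  }
})
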