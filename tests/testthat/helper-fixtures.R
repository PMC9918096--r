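# Shared fixture builders; everything is generated in code under fixed seeds.

random_counts <- function(n_mirna = 50, n_samples = 12, seed = 1,
                          lambda_range = c(1, 500)) {
  set.seed(seed)
  base <- exp(runif(n_mirna, log(lambda_range[1]), log(lambda_range[2])))
  m <- matrix(rpois(n_mirna * n_samples, rep(base, n_samples)),
              nrow = n_mirna,
              dimnames = list(sprintf("mir%03d", seq_len(n_mirna)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# small cohort for fast end-to-end tests
small_sim <- function(seed = 1, ...) {
  sim_config(n_naive = 4, n_sham = 5, n_tbi = 12, n_mirna = 80,
             n_injury_responsive = 8, seed = seed, ...)
}

# binormal two-class feature: separation d gives theoretical AUC pnorm(d/sqrt(2))
binormal_feature <- function(y, target_auc = 0.9) {
  d <- sqrt(2) * qnorm(target_auc)
  ifelse(y, d, 0) + rnorm(length(y))
}
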