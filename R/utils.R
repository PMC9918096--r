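# Internal helpers shared across modules.

# Round half away from zero (reporting convention for percentages and fold
# changes; base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Rank-based AUC of `values` for binary `labels` (TRUE/1 = positive class).
# Equals Mann-Whitney U / (n1 * n2) with average ranks, so ties score 1/2.
auc_rank <- function(values, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires both classes to be present", call. = FALSE)
  }
  r <- rank(values)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment for a binary label vector. Returns an integer
# vector of fold ids in 1..k; each class is spread as evenly as possible.
stratified_folds <- function(labels, k) {
  labels <- as.logical(labels)
  fold <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels == cls)
    if (length(idx)) {
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  fold
}

# Inverse-class-frequency observation weights, normalised to sum to n.
class_weights <- function(labels) {
  labels <- as.logical(labels)
  n <- length(labels)
  w <- ifelse(labels, n / (2 * sum(labels)), n / (2 * sum(!labels)))
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
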