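#' Median-of-ratios size factors
#'
#' Per-sample normalization factors robust to differential expression:
#' for each sample, the median across miRNAs of the ratio between its count
#' and the miRNA's geometric mean, computed over miRNAs with all-positive
#' counts. Factors are rescaled to geometric mean 1. When no miRNA has
#' positive counts in every sample, falls back to total-count scaling with a
#' warning.
#'
#' @param counts Raw count matrix (miRNAs x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no miRNA with positive counts in all samples; ",
            "falling back to total-count scaling")
    sf <- colSums(counts)
  } else {
    logc <- log(counts[pos, , drop = FALSE])
    loggm <- rowMeans(logc)
    sf <- apply(exp(logc - loggm), 2, stats::median)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Per-miRNA negative-binomial dispersion by method of moments
#'
#' Estimates the NB dispersion alpha (variance \code{mu + alpha mu^2}) for
#' each miRNA from size-factor-normalized counts. With a \code{groups}
#' vector, moments are computed within groups (so real group differences do
#' not inflate the estimate) and pooled with degrees-of-freedom weights. The
#' Poisson component of the variance of normalized counts,
#' \code{mu * mean(1/size_factor)}, is subtracted before forming alpha.
#'
#' @param counts Raw count matrix.
#' @param sf Size factors from [size_factors()].
#' @param groups Optional group labels (one per sample).
#' @param floor Lower bound for the returned dispersion (default 1e-8).
#' @return Data frame with \code{mirna_id} and \code{dispersion}.
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts),
                                groups = NULL, floor = 1e-8) {
  counts <- as.matrix(counts)
  q <- sweep(counts, 2, sf, "/")
  inv_s <- mean(1 / sf)
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) {
    bad <- names(which(table(groups) < 2))
    stop("dispersion estimation needs >= 2 samples per group; offending group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  excess_num <- rep(0, nrow(q))
  w_tot <- 0
  for (g in levels(groups)) {
    cols <- groups == g
    ng <- sum(cols)
    mu_g <- rowMeans(q[, cols, drop = FALSE])
    v_g <- apply(q[, cols, drop = FALSE], 1, stats::var)
    # excess variance over the Poisson/normalization component, per group
    ex <- (v_g - mu_g * inv_s) / pmax(mu_g, 1e-12)^2
    excess_num <- excess_num + (ng - 1) * ex
    w_tot <- w_tot + (ng - 1)
  }
  alpha <- pmax(floor, excess_num / w_tot)
  alpha[rowSums(counts) == 0] <- floor
  data.frame(mirna_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             dispersion = as.numeric(alpha), stringsAsFactors = FALSE)
}

# IRLS fit of a per-miRNA NB GLM with log link, fixed dispersion alpha and
# log size-factor offsets. X is the design matrix. Returns coefficients,
# their covariance, and a convergence flag.
nb_irls <- function(y, X, offset, alpha, tol = 1e-8, max_iter = 100L) {
  beta <- rep(0, ncol(X))
  mu0 <- mean(y / exp(offset))
  beta[1] <- log(max(mu0, 1e-8))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients))) break
    delta <- fit$coefficients - beta
    beta <- fit$coefficients
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, cov = cov, converged = converged)
}

#' Negative-binomial Wald test for differential expression
#'
#' A simplified stand-in for a DESeq2-style analysis: median-of-ratios size
#' factors, per-miRNA method-of-moments dispersion, a two-group NB GLM with
#' log link fitted by IRLS, a Wald test on the group coefficient, and
#' Benjamini-Hochberg adjustment across the tested miRNAs. No dispersion
#' shrinkage, independent filtering or LFC shrinkage is performed.
#'
#' @param counts Raw count matrix (miRNAs x samples).
#' @param groups Group label per sample.
#' @param contrast Character vector \code{c(group_a, group_b)}; positive
#'   log2 fold change means higher in \code{group_a}.
#' @param sf Optional precomputed size factors for the full matrix.
#' @param dispersion_floor Lower bound for dispersion estimates.
#' @return Object of classes \code{"de_result"} and \code{"data.frame"} with
#'   columns \code{mirna_id, base_mean, log2fc, se_log2fc, wald_stat,
#'   p_value, p_adj}, ordered as the input. miRNAs with zero reads in every
#'   selected sample are excluded (recorded in attribute
#'   \code{"excluded"}); non-converged fits get \code{NA} p-values.
#' @export
nb_wald_test <- function(counts, groups, contrast, sf = NULL,
                         dispersion_floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(contrast) == 2)
  sel <- groups %in% contrast
  if (!any(groups == contrast[1]) || !any(groups == contrast[2])) {
    stop("both contrast groups must be non-empty", call. = FALSE)
  }
  y <- counts[, sel, drop = FALSE]
  g <- groups[sel]
  if (min(table(g)) < 2) {
    stop("contrast ", paste(contrast, collapse = " vs "),
         " needs >= 2 samples per group", call. = FALSE)
  }
  excluded <- rownames(y)[rowSums(y) == 0]
  y <- y[rowSums(y) > 0, , drop = FALSE]
  if (is.null(sf)) sf <- size_factors(y)
  else sf <- sf[colnames(y)]
  disp <- estimate_dispersion(y, sf, groups = g, floor = dispersion_floor)
  X <- cbind(1, as.numeric(g == contrast[1]))
  off <- log(sf)
  nmir <- nrow(y)
  log2fc <- se <- stat <- p <- rep(NA_real_, nmir)
  for (i in seq_len(nmir)) {
    fit <- nb_irls(y[i, ], X, off, disp$dispersion[i])
    if (!fit$converged || !is.finite(fit$cov[2, 2])) next
    log2fc[i] <- fit$beta[2] / log(2)
    se[i] <- sqrt(fit$cov[2, 2]) / log(2)
    stat[i] <- fit$beta[2] / sqrt(fit$cov[2, 2])
    p[i] <- 2 * stats::pnorm(-abs(stat[i]))
  }
  res <- data.frame(
    mirna_id = rownames(y) %||% as.character(seq_len(nmir)),
    base_mean = rowMeans(sweep(y, 2, sf, "/")),
    log2fc = log2fc, se_log2fc = se, wald_stat = stat,
    p_value = p, p_adj = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "contrast") <- contrast
  attr(res, "excluded") <- excluded
  attr(res, "n_tested") <- nmir
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("NB Wald differential expression: %s vs %s\n", ct[1], ct[2]))
  cat(sprintf("  %d miRNAs tested, %d excluded (all-zero), %d shown with p_adj < 0.05\n",
              attr(x, "n_tested") %||% nrow(x), length(attr(x, "excluded")),
              sum(x$p_adj < 0.05, na.rm = TRUE)))
  NextMethod()
}
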