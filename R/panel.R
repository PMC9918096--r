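#' Configuration for the elastic-net panel procedure
#'
#' @param alpha Elastic-net mixing in [0, 1]; 0.5 weights the LASSO and
#'   Ridge penalties equally (the default used for biomarker panels).
#' @param lambda_grid Decreasing penalty grid; default 25 values spaced
#'   logarithmically over six decades.
#' @param class_weighting Weight observations inversely to class frequency
#'   to compensate for class imbalance (default TRUE).
#' @param n_boot Bootstrap resamples for the BCa confidence interval
#'   (default 10000).
#' @param inner_folds Stratified folds of the inner cross-validation that
#'   picks the penalty within each outer leave-one-out fold.
#' @param seed Optional integer seed controlling inner-fold assignment and
#'   the bootstrap.
#' @return Object of class \code{"panel_config"}.
#' @export
panel_config <- function(alpha = 0.5,
                         lambda_grid = 10^seq(1, -5, length.out = 25),
                         class_weighting = TRUE, n_boot = 10000,
                         inner_folds = 5, seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, n_boot >= 1, inner_folds >= 2)
  structure(list(alpha = alpha,
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 class_weighting = class_weighting,
                 n_boot = n_boot, inner_folds = inner_folds, seed = seed),
            class = "panel_config")
}

# glmnet refuses single-column x; pad with an all-zero dummy column, which
# can never receive a nonzero coefficient.
glmnet_safe <- function(x, ...) {
  padded <- ncol(x) == 1
  if (padded) x <- cbind(x, `.pad` = 0)
  fit <- glmnet::glmnet(x, ...)
  attr(fit, "padded") <- padded
  fit
}

predict_safe <- function(fit, newx, ...) {
  if (isTRUE(attr(fit, "padded"))) newx <- cbind(newx, `.pad` = 0)
  stats::predict(fit, newx = newx, ...)
}

# response-scale predictions for every lambda of the fit, computed densely
# (avoids the sparse-matrix overhead of predict.glmnet in tight CV loops)
glmnet_response_all <- function(fit, newx) {
  if (isTRUE(attr(fit, "padded"))) newx <- cbind(newx, 0)
  eta <- sweep(newx %*% as.matrix(fit$beta), 2, as.numeric(fit$a0), "+")
  1 / (1 + exp(-eta))
}

# coefficient vector (no intercept) at the fitted lambda closest to `lambda`
glmnet_coef_at <- function(fit, lambda) {
  li <- which.min(abs(fit$lambda - lambda))
  as.numeric(fit$beta[, li])
}

# |t|-score of each feature for a binary label (F-score filter ranking)
fscore_rank <- function(x, y) {
  y <- as.logical(y)
  m1 <- colMeans(x[y, , drop = FALSE]); m0 <- colMeans(x[!y, , drop = FALSE])
  v1 <- apply(x[y, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[!y, , drop = FALSE], 2, stats::var)
  s <- (m1 - m0)^2 / (v1 / sum(y) + v0 / sum(!y) + 1e-12)
  order(s, decreasing = TRUE)
}

# recursive feature elimination with a penalized logistic scorer: drop the
# feature with the smallest |coefficient| until k remain
rfe_select <- function(x, y, k, weights, penalty_alpha, lambda) {
  keep <- seq_len(ncol(x))
  while (length(keep) > k) {
    fit <- glmnet_safe(x[, keep, drop = FALSE], y = y, family = "binomial",
                       alpha = penalty_alpha, lambda = lambda,
                       weights = weights, standardize = FALSE)
    b <- abs(as.numeric(fit$beta[, ncol(fit$beta)]))[seq_along(keep)]
    keep <- keep[-which.min(b)]
  }
  keep
}

#' Nested leave-one-out logistic-regression discovery analysis
#'
#' Multivariate discovery of group-separating miRNAs: an outer
#' leave-one-out loop around an inner stratified cross-validation that
#' tunes, per outer fold, the feature-selection method and number of
#' features, the penalty type (L1 or L2), and the regularization level by
#' pooled inner AUC. Inside every training fold the features are
#' standardized to zero mean and unit variance (parameters estimated from
#' that fold only), zero-variance features are dropped, and selection uses
#' an F-score filter or recursive feature elimination. The cross-validated
#' AUC is the ROC AUC of the pooled held-out predicted probabilities;
#' feature importance is the mean absolute (standardized-scale) coefficient
#' over outer folds, normalized to sum to 1 and sorted descending.
#'
#' @param x Numeric matrix, samples x features (e.g. a prevalence-filtered
#'   count matrix, samples in rows).
#' @param y Binary outcome (logical or 0/1).
#' @param selection Selection methods in the tuning grid: subset of
#'   \code{c("fscore", "rfe")}. Default \code{"fscore"} (RFE is available
#'   but costs one penalized fit per eliminated feature).
#' @param k_grid Numbers of selected features to try; default
#'   \code{unique(c(1, ceiling(p/2), p))}.
#' @param penalties Subset of \code{c("l1", "l2")}.
#' @param lambda_grid Regularization levels; default six values spaced over
#'   six decades.
#' @param inner_folds Stratified inner folds (default 5).
#' @param class_weighting Inverse-class-frequency observation weights
#'   (default TRUE; keeps the pooled leave-one-out AUC calibrated at 0.5
#'   under the null when classes are imbalanced).
#' @param seed Optional seed for inner-fold assignment.
#' @return Object of class \code{"nested_cv"}: list with \code{cv_auc},
#'   \code{pooled_predictions} (one out-of-fold probability per sample),
#'   \code{feature_importance} (named, sums to 1, descending),
#'   \code{fold_detail} (chosen configuration, selected features and
#'   coefficients per outer fold), \code{y}.
#' @export
nested_loocv_logistic <- function(x, y,
                                  selection = "fscore",
                                  k_grid = NULL,
                                  penalties = c("l1", "l2"),
                                  lambda_grid = 10^seq(1, -4, length.out = 6),
                                  inner_folds = 5,
                                  class_weighting = TRUE,
                                  seed = NULL) {
  x <- as.matrix(x)
  y <- as.logical(y)
  stopifnot(nrow(x) == length(y), all(selection %in% c("fscore", "rfe")),
            all(penalties %in% c("l1", "l2")))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))
  if (is.null(k_grid)) k_grid <- unique(c(1, ceiling(p / 2), p))
  k_grid <- k_grid[k_grid >= 1 & k_grid <= p]
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  grid <- expand.grid(sel = selection, k = k_grid, pen = penalties,
                      stringsAsFactors = FALSE)

  pooled <- rep(NA_real_, n)
  abs_coef <- matrix(0, n, p, dimnames = list(NULL, colnames(x)))
  fold_detail <- vector("list", n)
  skipped <- 0L

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2) {
      warning("outer fold ", i, " lacks a class in training; skipped")
      skipped <- skipped + 1L
      next
    }
    xtr <- x[tr, , drop = FALSE]
    w <- if (class_weighting) class_weights(ytr) else rep(1, length(ytr))
    folds <- stratified_folds(ytr, inner_folds)

    # inner CV: pooled validation predictions per (config, lambda)
    inner_pred <- array(NA_real_,
                        dim = c(nrow(grid), length(ytr), length(lambda_grid)))
    for (f in sort(unique(folds))) {
      it <- folds != f; iv <- !it
      if (length(unique(ytr[it])) < 2) next
      ctr <- colMeans(xtr[it, , drop = FALSE])
      scl <- apply(xtr[it, , drop = FALSE], 2, stats::sd)
      usable <- which(scl > 0)
      if (!length(usable)) next
      zt <- scale(xtr[it, usable, drop = FALSE], ctr[usable], scl[usable])
      zv <- scale(xtr[iv, usable, drop = FALSE], ctr[usable], scl[usable])
      for (gi in seq_len(nrow(grid))) {
        k <- min(grid$k[gi], length(usable))
        pa <- if (grid$pen[gi] == "l1") 1 else 0
        selidx <- if (grid$sel[gi] == "fscore") {
          fscore_rank(zt, ytr[it])[seq_len(k)]
        } else {
          rfe_select(zt, ytr[it], k, w[it], pa, lambda_grid)
        }
        fit <- glmnet_safe(zt[, selidx, drop = FALSE], y = ytr[it],
                           family = "binomial", alpha = pa,
                           lambda = lambda_grid, weights = w[it],
                           standardize = FALSE, thresh = 1e-5)
        pr <- glmnet_response_all(fit, zv[, selidx, drop = FALSE])
        inner_pred[gi, iv, seq_len(ncol(pr))] <- pr[, , drop = FALSE]
      }
    }
    # score every (config, lambda) by pooled inner AUC
    best <- c(auc = -Inf, gi = 1, li = 1)
    for (gi in seq_len(nrow(grid))) {
      for (li in seq_along(lambda_grid)) {
        pp <- inner_pred[gi, , li]
        ok <- !is.na(pp)
        if (sum(ok) < 2 || length(unique(ytr[ok])) < 2) next
        a <- auc_rank(pp[ok], ytr[ok])
        # ties: prefer stronger regularization, then fewer features
        if (a > best["auc"] + 1e-12) best <- c(auc = a, gi = gi, li = li)
      }
    }
    gi <- best["gi"]; li <- best["li"]

    # refit the chosen configuration on the full training fold
    ctr <- colMeans(xtr)
    scl <- apply(xtr, 2, stats::sd)
    usable <- which(scl > 0)
    zt <- scale(xtr[, usable, drop = FALSE], ctr[usable], scl[usable])
    zh <- scale(x[i, usable, drop = FALSE], ctr[usable], scl[usable])
    k <- min(grid$k[gi], length(usable))
    pa <- if (grid$pen[gi] == "l1") 1 else 0
    selidx <- if (grid$sel[gi] == "fscore") {
      fscore_rank(zt, ytr)[seq_len(k)]
    } else {
      rfe_select(zt, ytr, k, w, pa, lambda_grid)
    }
    fit <- glmnet_safe(zt[, selidx, drop = FALSE], y = ytr,
                       family = "binomial", alpha = pa,
                       lambda = lambda_grid, weights = w,
                       standardize = FALSE, thresh = 1e-5)
    li_fit <- which.min(abs(fit$lambda - lambda_grid[li]))
    pooled[i] <- glmnet_response_all(fit, zh[, selidx, drop = FALSE])[1, li_fit]
    b <- glmnet_coef_at(fit, lambda_grid[li])
    feats <- colnames(x)[usable][selidx]
    abs_coef[i, feats] <- abs(b[seq_along(selidx)])
    fold_detail[[i]] <- list(config = grid[gi, ], lambda = lambda_grid[li],
                             inner_auc = unname(best["auc"]),
                             features = feats,
                             coefficients = stats::setNames(b[seq_along(selidx)], feats))
  }
  if (skipped == n) stop("every outer fold failed", call. = FALSE)

  imp <- colMeans(abs_coef[!is.na(pooled), , drop = FALSE])
  if (sum(imp) > 0) imp <- imp / sum(imp)
  else imp <- structure(rep(1 / p, p), names = colnames(x))
  imp <- sort(imp, decreasing = TRUE)
  ok <- !is.na(pooled)
  structure(list(cv_auc = auc_rank(pooled[ok], y[ok]),
                 pooled_predictions = pooled,
                 feature_importance = imp,
                 fold_detail = fold_detail,
                 y = y),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("Nested leave-one-out logistic discovery (n = %d)\n", length(x$y)))
  cat(sprintf("  pooled CV AUC: %.3f\n", x$cv_auc))
  top <- utils::head(x$feature_importance, 5)
  cat("  top feature importance:\n")
  for (nm in names(top)) cat(sprintf("    %-20s %.3f\n", nm, top[nm]))
  invisible(x)
}

#' @export
summary.nested_cv <- function(object, ...) {
  print(object)
  cfgs <- t(vapply(object$fold_detail[!vapply(object$fold_detail, is.null, TRUE)],
                   function(d) c(sel = d$config$sel, k = as.character(d$config$k),
                                 pen = d$config$pen), character(3)))
  cat("  chosen configurations over outer folds:\n")
  print(table(apply(cfgs, 1, paste, collapse = "/")))
  invisible(object)
}

#' Elastic-net miRNA panel selection with majority-zero exclusion
#'
#' The two-stage panel procedure. Stage 1: an outer leave-one-out loop; in
#' each fold a weighted elastic-net logistic regression (mixing
#' \code{alpha}, observation weights inverse to class frequency) is fitted
#' over the penalty grid, the penalty is chosen by inner stratified
#' cross-validation minimizing weighted binomial deviance, and the zero
#' pattern of the coefficients is recorded. Features whose coefficient is
#' zero in more than half of the outer folds are excluded. Stage 2: the
#' surviving panel is refitted by ordinary (unpenalized) logistic
#' regression with leave-one-out pooled CV AUC ([refit_logistic_cv_auc()])
#' and a 95\% BCa bootstrap confidence interval for that AUC
#' ([bca_bootstrap_ci()]).
#'
#' @param x Numeric matrix, samples x features (normalized expression).
#' @param y Binary outcome.
#' @param config A [panel_config()].
#' @param refit Run stage 2 when the kept set is non-empty (default TRUE).
#' @return Object of class \code{"panel_fit"}: list with
#'   \code{kept_features}, \code{fold_coefficients} (outer folds x
#'   features), \code{zero_fraction} per feature, stage-1
#'   \code{cv_auc_penalized} and \code{pooled_penalized}, and — when a
#'   panel survives — \code{refit} (coefficients, p-values),
#'   \code{cv_auc}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{pooled_predictions}. An empty panel is flagged via
#'   \code{empty_panel = TRUE}.
#' @export
panel_select <- function(x, y, config = panel_config(), refit = TRUE) {
  stopifnot(inherits(config, "panel_config"))
  x <- as.matrix(x)
  y <- as.logical(y)
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))
  if (min(table(y)) < 2) stop("need >= 2 samples per class", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  lambda_grid <- config$lambda_grid

  fold_coef <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(x)))
  pooled <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2) { warning("outer fold ", i, " skipped"); next }
    xtr <- x[tr, , drop = FALSE]
    w <- if (config$class_weighting) class_weights(ytr) else rep(1, length(ytr))
    folds <- stratified_folds(ytr, config$inner_folds)
    fold_ids <- sort(unique(folds))
    dev <- matrix(NA_real_, length(fold_ids), length(lambda_grid))
    for (fi in seq_along(fold_ids)) {
      it <- folds != fold_ids[fi]; iv <- !it
      if (length(unique(ytr[it])) < 2) next
      fit <- glmnet_safe(xtr[it, , drop = FALSE], y = ytr[it],
                         family = "binomial", alpha = config$alpha,
                         lambda = lambda_grid, weights = w[it])
      pr <- glmnet_response_all(fit, xtr[iv, , drop = FALSE])
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      yv <- ytr[iv]; wv <- w[iv]
      dev[fi, ] <- vapply(seq_len(ncol(pr)), function(li) {
        -2 * sum(wv * (yv * log(pr[, li]) + (1 - yv) * log(1 - pr[, li]))) / sum(wv)
      }, numeric(1))
    }
    # one-SE rule: strongest penalty whose CV deviance is within one standard
    # error of the minimum (the sparsity-favoring glmnet convention)
    mdev <- colMeans(dev, na.rm = TRUE)
    li_min <- which.min(mdev)
    se_min <- stats::sd(dev[, li_min], na.rm = TRUE) /
      sqrt(sum(!is.na(dev[, li_min])))
    li <- which(mdev <= mdev[li_min] + se_min)[1]  # lambdas are decreasing
    fit <- glmnet_safe(xtr, y = ytr, family = "binomial",
                       alpha = config$alpha, lambda = lambda_grid, weights = w)
    b <- glmnet_coef_at(fit, lambda_grid[li])
    fold_coef[i, ] <- b[seq_len(p)]
    li_fit <- which.min(abs(fit$lambda - lambda_grid[li]))
    pooled[i] <- glmnet_response_all(fit, x[i, , drop = FALSE])[1, li_fit]
  }
  done <- !is.na(pooled)
  zero_frac <- colMeans(fold_coef[done, , drop = FALSE] == 0)
  kept <- colnames(x)[zero_frac <= 0.5]   # excluded iff zero in the majority
  res <- list(kept_features = kept,
              fold_coefficients = fold_coef,
              zero_fraction = zero_frac,
              cv_auc_penalized = auc_rank(pooled[done], y[done]),
              pooled_penalized = pooled,
              empty_panel = length(kept) == 0,
              config = config, y = y)
  if (length(kept) == 0) {
    warning("no predictor survived the majority-zero rule: empty panel")
  } else if (refit) {
    rf <- refit_logistic_cv_auc(x[, kept, drop = FALSE], y)
    ci <- bca_bootstrap_ci(rf$pooled_predictions, y,
                           n_boot = config$n_boot)
    res$refit <- rf$coefficients
    res$cv_auc <- rf$cv_auc
    res$pooled_predictions <- rf$pooled_predictions
    res$ci_low <- ci$ci_low
    res$ci_high <- ci$ci_high
    res$p_value <- mann_whitney(rf$pooled_predictions[y],
                                rf$pooled_predictions[!y])$p_value
  }
  structure(res, class = "panel_fit")
}

#' @export
print.panel_fit <- function(x, ...) {
  cat(sprintf("Elastic-net panel selection (n = %d, %d candidate features)\n",
              length(x$y), ncol(x$fold_coefficients)))
  if (x$empty_panel) {
    cat("  no combination selected: all coefficients zero in the majority of folds\n")
  } else {
    cat("  kept panel:", paste(x$kept_features, collapse = ", "), "\n")
    if (!is.null(x$cv_auc)) {
      cat(sprintf("  refit pooled CV AUC: %.2f (95%% BCa CI %.2f-%.2f, p = %.3g)\n",
                  x$cv_auc, x$ci_low, x$ci_high, x$p_value))
    }
  }
  invisible(x)
}

#' Unpenalized logistic refit with pooled leave-one-out CV AUC
#'
#' Fits a standard logistic regression on the kept panel, reporting
#' per-coefficient Wald p-values from the full-data fit, and computes the
#' cross-validated AUC by refitting the model in every leave-one-out fold
#' and pooling the held-out predicted probabilities into a single ROC.
#'
#' @param x Numeric matrix, samples x kept features.
#' @param y Binary outcome.
#' @return List with \code{cv_auc}, \code{pooled_predictions},
#'   \code{coefficients} (data frame \code{term, estimate, se, p_value};
#'   non-finite estimates indicate separation) and \code{separation} flag.
#' @export
refit_logistic_cv_auc <- function(x, y) {
  x <- as.matrix(x)
  y <- as.logical(y)
  n <- nrow(x)
  df <- data.frame(y = y, x, check.names = TRUE)
  full <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  sm <- summary(full)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      p_value = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  separation <- any(abs(sm[, 1]) > 15) || !full$converged
  pooled <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(stats::glm(y ~ ., data = df[-i, , drop = FALSE],
                                       family = stats::binomial()))
    pooled[i] <- suppressWarnings(
      stats::predict(fit, newdata = df[i, , drop = FALSE], type = "response"))
  }
  list(cv_auc = auc_rank(pooled, y),
       pooled_predictions = pooled,
       coefficients = coefs,
       separation = separation)
}

#' BCa bootstrap confidence interval for a pooled-prediction statistic
#'
#' Bias-corrected and accelerated bootstrap interval for a statistic of
#' (predictions, labels) pairs — by default the ROC AUC. Samples are
#' resampled with replacement; the bias correction z0 comes from the
#' fraction of bootstrap statistics below the point estimate (ties counted
#' half), and the acceleration from the jackknife skewness.
#'
#' @param predictions,labels Pooled out-of-fold predictions and true binary
#'   labels.
#' @param statistic Function \code{(values, labels) -> scalar}; default the
#'   rank AUC.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return List with \code{ci_low}, \code{ci_high}, \code{t0}, \code{z0},
#'   \code{accel}, \code{boot_stats} (resamples that retained both
#'   classes), and \code{degenerate} (TRUE when the bootstrap distribution
#'   collapses to a point, in which case the CI equals the estimate).
#' @export
bca_bootstrap_ci <- function(predictions, labels, statistic = auc_rank,
                             n_boot = 10000, level = 0.95, seed = NULL) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(predictions)
  t0 <- statistic(predictions, labels)
  tb <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    lb <- labels[idx]
    if (!any(lb) || all(lb)) next
    tb[b] <- statistic(predictions[idx], lb)
  }
  tb <- tb[!is.na(tb)]
  if (length(unique(tb)) == 1L) {
    return(list(ci_low = t0, ci_high = t0, t0 = t0, z0 = 0, accel = 0,
                boot_stats = tb, degenerate = TRUE))
  }
  pb <- (sum(tb < t0) + 0.5 * sum(tb == t0)) / length(tb)
  pb <- min(max(pb, 1 / (length(tb) + 1)), 1 - 1 / (length(tb) + 1))
  z0 <- stats::qnorm(pb)
  # jackknife acceleration
  tj <- vapply(seq_len(n), function(i) {
    lb <- labels[-i]
    if (!any(lb) || all(lb)) return(NA_real_)
    statistic(predictions[-i], lb)
  }, numeric(1))
  tj <- tj[!is.na(tj)]
  d <- mean(tj) - tj
  accel <- if (sum(d^2) == 0) 0 else sum(d^3) / (6 * sum(d^2)^1.5)
  alpha <- (1 - level) / 2
  zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - accel * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - accel * (z0 + zu)))
  ci <- stats::quantile(tb, probs = c(a1, a2), names = FALSE, type = 7)
  list(ci_low = ci[1], ci_high = ci[2], t0 = t0, z0 = z0, accel = accel,
       boot_stats = tb, degenerate = FALSE)
}

#' @export
coef.panel_fit <- function(object, ...) {
  if (object$empty_panel || is.null(object$refit)) return(NULL)
  stats::setNames(object$refit$estimate, object$refit$term)
}

#' @export
coef.nested_cv <- function(object, ...) object$feature_importance
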