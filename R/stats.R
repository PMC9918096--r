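#' Kruskal-Wallis rank-sum test across three or more groups
#'
#' Tie-corrected H statistic with a chi-square approximation for the
#' p-value. For two groups use [mann_whitney()].
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 3 non-empty groups).
#' @return List with \code{statistic} (H), \code{df}, \code{p_value},
#'   \code{groups} and \code{n} per group.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 3) {
    stop("fewer than 3 groups: use mann_whitney() for two-group comparisons",
         call. = FALSE)
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, groups = levels(groups),
       n = as.integer(table(groups)))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration when both groups have fewer than \code{exact_below}
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction (no continuity correction, so that U relates exactly
#' to the ROC AUC).
#'
#' @param a,b Numeric vectors.
#' @param exact_below Exact p-values when both n are below this and the data
#'   are tie-free.
#' @return List with \code{statistic} (U for "a ahead of b", with average
#'   ranks so ties count 1/2), \code{p_value}, \code{n}, \code{exact}.
#' @export
mann_whitney <- function(a, b, exact_below = 20) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) < exact_below && length(b) < exact_below && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  list(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
       n = c(length(a), length(b)), exact = exact)
}

#' Fold change between group means
#'
#' Ratio of means, rounded half-up to one decimal (the reporting convention
#' for validated biomarkers), or a rounded percentage when
#' \code{percent = TRUE}. The unrounded ratio is kept in attribute
#' \code{"raw"}.
#'
#' @param a,b Numeric vectors (or single precomputed means); the fold is
#'   \code{mean(a) / mean(b)}.
#' @param percent Report \code{round(100 * ratio)} instead.
#' @return Rounded fold change (or percent) with attribute \code{"raw"}.
#' @examples
#' fold_change(1.41, 0.33)  # 4.3
#' @export
fold_change <- function(a, b, percent = FALSE) {
  ma <- mean(a, na.rm = TRUE); mb <- mean(b, na.rm = TRUE)
  if (mb == 0) {
    warning("zero denominator mean: fold change undefined")
    return(structure(NA_real_, raw = NA_real_))
  }
  r <- ma / mb
  out <- if (percent) round_half_up(100 * r) else round_half_up(r, 1)
  structure(out, raw = r)
}

#' ROC curve, AUC and optimal cutpoint
#'
#' Rank-based AUC (identical to Mann-Whitney U / (n1 n2); ties score 1/2),
#' the full sensitivity/specificity curve over all observed thresholds, the
#' cutpoint maximizing sensitivity + specificity, and a two-sided
#' Mann-Whitney p-value for the AUC. Orientation is fixed: higher values
#' predict the positive class, so an anti-discriminating marker yields
#' AUC < 0.5 (not flipped).
#'
#' @param values Marker values.
#' @param labels Binary labels (TRUE/1 = positive class).
#' @param direction \code{">="} (positive if value >= cutoff; default, for
#'   upregulated markers) or \code{"<="} for downregulated markers.
#' @return Object of class \code{"roc_result"}: list with \code{auc},
#'   \code{p_value}, \code{cutoff}, \code{sensitivity}, \code{specificity},
#'   \code{curve} (data frame \code{cutoff, sensitivity, specificity}),
#'   \code{n}.
#' @export
roc_curve <- function(values, labels, direction = ">=") {
  labels <- as.logical(labels)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) {
    stop("ROC requires both classes to be present", call. = FALSE)
  }
  auc <- auc_rank(values, labels)
  mw <- mann_whitney(values[labels], values[!labels])
  cut <- optimal_cutpoint(values, labels, direction = direction)
  thr <- sort(unique(values))
  curve <- do.call(rbind, lapply(thr, function(cc) {
    pred <- if (direction == ">=") values >= cc else values <= cc
    data.frame(cutoff = cc,
               sensitivity = mean(pred[labels]),
               specificity = mean(!pred[!labels]))
  }))
  structure(list(auc = auc, p_value = mw$p_value,
                 cutoff = cut$cutoff, sensitivity = cut$sensitivity,
                 specificity = cut$specificity, curve = curve,
                 n = c(positive = sum(labels), negative = sum(!labels))),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (p = %.3g), cutoff %.4g -> sens %.0f%%, spec %.0f%% (n+ = %d, n- = %d)\n",
              x$auc, x$p_value, x$cutoff, 100 * x$sensitivity,
              100 * x$specificity, x$n["positive"], x$n["negative"]))
  invisible(x)
}

#' Optimal ROC cutpoint maximizing sensitivity + specificity
#'
#' Evaluates every observed marker value as a candidate threshold
#' (classification rule: positive if value >= cutoff, or <= for
#' downregulated markers) and returns the maximizer of
#' sensitivity + specificity (the Youden criterion). Ties are broken toward
#' higher specificity, then toward the lower cutoff.
#'
#' @inheritParams roc_curve
#' @return List with \code{cutoff}, \code{sensitivity}, \code{specificity}.
#' @export
optimal_cutpoint <- function(values, labels, direction = ">=") {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("cutpoint requires both classes to be present", call. = FALSE)
  }
  thr <- sort(unique(values))
  best <- NULL
  for (cc in thr) {
    pred <- if (direction == ">=") values >= cc else values <= cc
    sens <- mean(pred[labels])
    spec <- mean(!pred[!labels])
    cand <- c(sum = sens + spec, spec = spec, cutoff = cc, sens = sens)
    if (is.null(best) ||
        cand["sum"] > best["sum"] + 1e-12 ||
        (abs(cand["sum"] - best["sum"]) <= 1e-12 &&
         (cand["spec"] > best["spec"] + 1e-12 ||
          (abs(cand["spec"] - best["spec"]) <= 1e-12 && cc < best["cutoff"])))) {
      best <- cand
    }
  }
  list(cutoff = unname(best["cutoff"]),
       sensitivity = unname(best["sens"]),
       specificity = unname(best["spec"]))
}

#' Spearman rank correlation
#'
#' Average-rank (tie-aware) Spearman rho with a two-sided p-value from the
#' asymptotic t approximation. Pairs with missing values are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @param min_n Minimum number of complete pairs (default 5); fewer pairs
#'   return \code{NA} with a warning.
#' @return List with \code{rho}, \code{p_value}, \code{n}.
#' @export
spearman_cor <- function(x, y, min_n = 5) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n) {
    warning("fewer than ", min_n, " complete pairs; correlation flagged")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}
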