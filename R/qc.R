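#' Counts-per-million normalization
#'
#' Scales each sample (column) of a raw miRNA count matrix so that its reads
#' sum to one million: \code{CPM = count / sample total * 1e6}.
#'
#' @param counts Non-negative integer matrix, miRNAs in rows, samples in
#'   columns, with row and column names.
#' @return Numeric matrix of the same dimensions; every column sums to 1e6.
#' @examples
#' m <- matrix(c(1, 3, 6), ncol = 1, dimnames = list(paste0("mir", 1:3), "s1"))
#' cpm_normalize(m)
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0] %||% which(totals == 0)
    stop("sample(s) with zero total reads cannot be CPM-normalized: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Hemolysis quality control for plasma samples
#'
#' A plasma sample qualifies for downstream PCR analysis when its hemoglobin
#' absorbance at 414 nm is strictly below the threshold (default 0.25 AU,
#' samples at or above it are considered hemolyzed) and sufficient plasma
#' volume is available.
#'
#' @param meta Data frame with columns \code{sample_id}, \code{a414} and
#'   optionally \code{plasma_volume_ok} (assumed \code{TRUE} when absent).
#' @param threshold Absorbance cut; samples with \code{a414 >= threshold} fail.
#' @param drop_unevaluable If \code{TRUE}, samples with missing \code{a414}
#'   are removed from the denominator of the summary percentage; otherwise
#'   they count as unqualified.
#' @return List with \code{qualified} (named logical, \code{NA} when
#'   unevaluable), \code{n_qualified}, \code{n_total} and \code{percent}
#'   (rounded half-up to an integer).
#' @export
hemolysis_qc <- function(meta, threshold = 0.25, drop_unevaluable = FALSE) {
  stopifnot(is.data.frame(meta), "a414" %in% names(meta))
  vol_ok <- if ("plasma_volume_ok" %in% names(meta)) meta$plasma_volume_ok else TRUE
  qualified <- meta$a414 < threshold & vol_ok
  names(qualified) <- meta$sample_id
  n_total <- if (drop_unevaluable) sum(!is.na(qualified)) else length(qualified)
  n_q <- sum(qualified, na.rm = TRUE)
  list(
    qualified = qualified,
    n_qualified = n_q,
    n_total = n_total,
    percent = as.integer(round_half_up(100 * n_q / n_total))
  )
}

#' Per-group miRNA detection sets and their intersections
#'
#' A miRNA counts as detected in a group when it has at least one raw read in
#' at least one sample of that group. Returns the per-group sets together
#' with all pairwise and higher-order intersections (Venn regions).
#'
#' @param counts Raw count matrix (miRNAs x samples).
#' @param groups Factor or character vector of group labels, one per sample
#'   (column).
#' @return List with \code{sets} (named list of detected miRNA ids per
#'   group), \code{sizes}, \code{intersections} (named list over every group
#'   combination, names joined by \code{"&"}), and \code{exclusive} (miRNAs
#'   detected in exactly that combination of groups and no other).
#' @export
detection_sets <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  stopifnot(length(groups) == ncol(counts))
  lv <- levels(groups)
  sets <- lapply(lv, function(g) {
    cols <- which(groups == g)
    if (!length(cols)) {
      warning("group '", g, "' has no samples; empty detection set")
      return(character(0))
    }
    rownames(counts)[rowSums(counts[, cols, drop = FALSE] >= 1) >= 1]
  })
  names(sets) <- lv
  combos <- unlist(lapply(2:max(2, length(lv)), function(k) {
    if (k > length(lv)) return(NULL)
    utils::combn(lv, k, simplify = FALSE)
  }), recursive = FALSE)
  intersections <- lapply(combos, function(cc) Reduce(intersect, sets[cc]))
  names(intersections) <- vapply(combos, paste, "", collapse = "&")
  all_det <- Reduce(union, sets)
  membership <- vapply(sets, function(s) all_det %in% s, logical(length(all_det)))
  if (length(all_det) == 1L) membership <- matrix(membership, nrow = 1)
  key <- apply(membership, 1, function(m) paste(lv[m], collapse = "&"))
  exclusive <- split(all_det, key)
  list(
    sets = sets,
    sizes = vapply(sets, length, integer(1)),
    intersections = intersections,
    exclusive = exclusive,
    n_detected = length(all_det)
  )
}

#' Read-prevalence filter
#'
#' Keeps miRNAs with at least \code{min_count} reads in at least
#' \code{ceiling(min_fraction * n_samples)} samples (default: >= 1 read in
#' >= 80\% of samples), the prevalence rule used before multivariate
#' discovery analysis.
#'
#' @param counts Raw count matrix (miRNAs x samples).
#' @param min_count Minimum per-sample read count for a miRNA to count as
#'   present in that sample.
#' @param min_fraction Minimum fraction of samples in which the miRNA must be
#'   present; in (0, 1].
#' @return The filtered count matrix (possibly with zero rows).
#' @export
prevalence_filter <- function(counts, min_count = 1, min_fraction = 0.8) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  counts <- as.matrix(counts)
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  counts[keep, , drop = FALSE]
}

#' PCA summary of normalized expression
#'
#' Principal components of samples from a CPM matrix. Values are transformed
#' to \code{log2(CPM + 1)} by default and centered per miRNA; components are
#' returned with the percentage of variance each explains.
#'
#' @param cpm CPM matrix (miRNAs x samples).
#' @param log_transform Apply \code{log2(x + 1)} before PCA (default TRUE).
#' @return List with \code{scores} (samples x components), \code{percent_var}
#'   (non-increasing, sums to <= 100) and \code{sdev}.
#' @export
pca_summary <- function(cpm, log_transform = TRUE) {
  x <- as.matrix(cpm)
  if (ncol(x) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  if (log_transform) x <- log2(x + 1)
  xt <- t(x)                      # samples x miRNAs
  xt <- scale(xt, center = TRUE, scale = FALSE)
  total_var <- sum(apply(xt, 2, stats::var))
  if (total_var == 0) {
    k <- min(dim(xt))
    return(list(
      scores = matrix(0, nrow(xt), k, dimnames = list(rownames(xt), paste0("PC", seq_len(k)))),
      percent_var = rep(0, k),
      sdev = rep(0, k)
    ))
  }
  p <- stats::prcomp(xt, center = FALSE, scale. = FALSE)
  pv <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, percent_var = pv, sdev = p$sdev)
}
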