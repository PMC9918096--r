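#' Normal T2 band from control animals
#'
#' Pools the masked cortical voxels of all control (sham-operated) volumes
#' across all timepoints and returns the 2.5th and 97.5th percentiles as
#' the normal T2 range. Percentiles use linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @param control_volumes List of \code{t2_volume} objects (see
#'   [simulate_t2_volume()] or [as_t2_volume()]).
#' @param probs Percentile pair (default \code{c(0.025, 0.975)}).
#' @return Object of class \code{"lesion_band"}: list with \code{lower_ms},
#'   \code{upper_ms}, \code{n_voxels}, \code{degenerate} (TRUE when the
#'   band has zero width).
#' @export
normal_t2_band <- function(control_volumes, probs = c(0.025, 0.975)) {
  if (inherits(control_volumes, "t2_volume")) control_volumes <- list(control_volumes)
  pool <- unlist(lapply(control_volumes, function(v) v$t2[v$mask]))
  if (!length(pool)) stop("no masked control voxels to pool", call. = FALSE)
  q <- stats::quantile(pool, probs = probs, names = FALSE, type = 7)
  deg <- q[1] >= q[2]
  if (deg) warning("degenerate band: lower limit equals upper limit")
  structure(list(lower_ms = q[1], upper_ms = q[2], n_voxels = length(pool),
                 degenerate = deg),
            class = "lesion_band")
}

#' @export
print.lesion_band <- function(x, ...) {
  cat(sprintf("Normal T2 band: %.1f-%.1f ms (pooled over %d control voxels)\n",
              x$lower_ms, x$upper_ms, x$n_voxels))
  invisible(x)
}

#' Cortical lesion volume from a quantitative T2 map
#'
#' Classifies every masked voxel as normal when its T2 lies inside the band
#' (endpoints inclusive: \code{lower <= T2 <= upper} is normal) and
#' abnormal otherwise; the lesion volume is the abnormal voxel count times
#' the voxel volume. Below-band (hemorrhage-like) and above-band
#' (edema-like) voxels are reported separately.
#'
#' @param volume A \code{t2_volume} object.
#' @param band A [normal_t2_band()] result (or list with \code{lower_ms},
#'   \code{upper_ms}).
#' @return List with \code{volume_mm3}, \code{n_abnormal}, \code{n_below},
#'   \code{n_above}, \code{n_masked}.
#' @export
lesion_volume <- function(volume, band) {
  stopifnot(band$lower_ms < band$upper_ms || isTRUE(band$degenerate))
  t2 <- volume$t2[volume$mask]
  below <- t2 < band$lower_ms
  above <- t2 > band$upper_ms
  n_ab <- sum(below) + sum(above)
  list(volume_mm3 = n_ab * volume$voxel_volume_mm3,
       n_abnormal = n_ab, n_below = sum(below), n_above = sum(above),
       n_masked = length(t2))
}

#' Build a t2_volume from a voxel table
#'
#' Constructs the container used by [lesion_volume()] from a long voxel
#' table (columns \code{x, y, z, t2_ms} and optionally \code{in_mask}).
#'
#' @param voxels Data frame of voxel coordinates and T2 values (ms).
#' @param voxel_volume_mm3 Volume of one voxel.
#' @param sample_id,timepoint Identifiers carried along.
#' @return Object of class \code{"t2_volume"}.
#' @export
as_t2_volume <- function(voxels, voxel_volume_mm3, sample_id = NA_character_,
                         timepoint = NA_character_) {
  stopifnot(all(c("x", "y", "z", "t2_ms") %in% names(voxels)))
  dims <- c(max(voxels$x), max(voxels$y), max(voxels$z))
  t2 <- array(NA_real_, dims)
  mask <- array(FALSE, dims)
  idx <- cbind(voxels$x, voxels$y, voxels$z)
  t2[idx] <- voxels$t2_ms
  mask[idx] <- if ("in_mask" %in% names(voxels)) as.logical(voxels$in_mask) else TRUE
  structure(list(t2 = t2, mask = mask, lesion = NULL,
                 voxel_volume_mm3 = voxel_volume_mm3,
                 sample_id = sample_id, timepoint = timepoint),
            class = "t2_volume")
}

#' Correlate plasma miRNA levels with lesion metrics
#'
#' Spearman correlation between per-animal biomarker levels and a lesion
#' metric (T2 lesion volume per timepoint, or a histological lesion area),
#' one row per miRNA x timepoint. Pairs with missing values are dropped
#' pairwise; rows with fewer than 5 pairs are flagged with \code{NA}.
#'
#' @param levels Numeric matrix, animals x miRNAs (normalized expression),
#'   with row names identifying animals.
#' @param lesion Data frame with columns \code{sample_id}, \code{timepoint}
#'   and \code{value} (e.g. lesion volume in mm^3 or area in mm^2).
#' @return Data frame \code{mirna_id, timepoint, rho, p_value, n}.
#' @export
correlate_biomarker_lesion <- function(levels, lesion) {
  levels <- as.matrix(levels)
  stopifnot(!is.null(rownames(levels)),
            all(c("sample_id", "timepoint", "value") %in% names(lesion)))
  out <- list()
  for (tp in unique(lesion$timepoint)) {
    sub <- lesion[lesion$timepoint == tp, ]
    common <- intersect(rownames(levels), sub$sample_id)
    vals <- sub$value[match(common, sub$sample_id)]
    for (m in colnames(levels)) {
      sc <- suppressWarnings(spearman_cor(levels[common, m], vals))
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = m, timepoint = tp, rho = sc$rho, p_value = sc$p_value,
        n = sc$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
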