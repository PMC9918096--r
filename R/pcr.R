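#' qPCR relative quantification by 2^-dCt
#'
#' Normalizes a target assay to an endogenous reference on the cycle
#' threshold scale: \code{2^-(Ct_target - Ct_reference)}. Technical
#' replicates should be averaged on the Ct scale before the transform (done
#' automatically when vectors carry replicate values via \code{replicate}).
#'
#' @param ct_target,ct_reference Positive Ct values (vectors are paired).
#' @return Relative expression value(s); \code{NA} where either Ct is
#'   missing (excluded samples are recorded in attribute
#'   \code{"excluded"}).
#' @examples
#' delta_ct_normalize(25, 22)   # 2^-3 = 0.125
#' @export
delta_ct_normalize <- function(ct_target, ct_reference) {
  if (any(ct_target <= 0, na.rm = TRUE) || any(ct_reference <= 0, na.rm = TRUE)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  out <- 2^-(ct_target - ct_reference)
  excl <- which(is.na(ct_target) | is.na(ct_reference))
  if (length(excl)) attr(out, "excluded") <- excl
  out
}

#' Normalize a qPCR Ct table against a reference assay
#'
#' Averages replicate Ct values per sample and assay, then computes
#' \code{2^-dCt} of every non-reference assay against the reference.
#'
#' @param ct_table Data frame with columns \code{sample_id, assay_id, ct}.
#' @param reference_assay Assay id of the endogenous control.
#' @return Data frame \code{sample_id, assay_id, rel_expr}; samples without
#'   a reference Ct are excluded and listed in attribute \code{"excluded"}.
#' @export
qpcr_normalize <- function(ct_table, reference_assay) {
  stopifnot(all(c("sample_id", "assay_id", "ct") %in% names(ct_table)))
  agg <- stats::aggregate(ct ~ sample_id + assay_id, ct_table, mean)
  ref <- agg[agg$assay_id == reference_assay, c("sample_id", "ct")]
  tgt <- agg[agg$assay_id != reference_assay, ]
  ref_ct <- ref$ct[match(tgt$sample_id, ref$sample_id)]
  excluded <- unique(tgt$sample_id[is.na(ref_ct)])
  keep <- !is.na(ref_ct)
  out <- data.frame(sample_id = tgt$sample_id[keep],
                    assay_id = tgt$assay_id[keep],
                    rel_expr = as.numeric(delta_ct_normalize(tgt$ct[keep], ref_ct[keep])),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Poisson-corrected ddPCR concentration
#'
#' Converts droplet counts to an absolute concentration:
#' \code{-ln(1 - positives/total) / droplet_volume} copies/uL.
#'
#' @param positives,total Positive and total droplet counts (vectorized).
#' @param droplet_volume Droplet volume in microliters.
#' @return Concentration(s) in copies/uL. Zero positives yield 0 with a
#'   logical \code{"below_lod"} attribute; saturated wells
#'   (\code{positives == total}) raise an error.
#' @export
droplet_to_concentration <- function(positives, total, droplet_volume) {
  stopifnot(droplet_volume > 0, all(total > 0), all(positives >= 0))
  if (any(positives > total)) stop("positives cannot exceed total", call. = FALSE)
  if (any(positives == total)) {
    stop("saturated well (all droplets positive): concentration not estimable",
         call. = FALSE)
  }
  conc <- -log(1 - positives / total) / droplet_volume
  attr(conc, "below_lod") <- positives == 0
  conc
}

#' Merge replicate ddPCR wells
#'
#' Pools droplet counts across replicate wells of the same sample and assay
#' before Poisson correction (more stable than averaging per-well
#' concentrations).
#'
#' @param ddpcr Data frame with \code{sample_id, assay_id, positives, total,
#'   droplet_volume}.
#' @return One row per sample x assay with pooled counts and the
#'   Poisson-corrected \code{concentration}.
#' @export
merge_ddpcr_wells <- function(ddpcr) {
  stopifnot(all(c("sample_id", "assay_id", "positives", "total",
                  "droplet_volume") %in% names(ddpcr)))
  agg <- stats::aggregate(cbind(positives, total) ~ sample_id + assay_id +
                            droplet_volume, ddpcr, sum)
  agg$concentration <- as.numeric(
    droplet_to_concentration(agg$positives, agg$total, agg$droplet_volume))
  agg
}

#' ddPCR target/reference normalization
#'
#' Relative expression as the ratio of the target concentration to the
#' reference-assay concentration of the same sample.
#'
#' @param target_conc,reference_conc Concentrations in copies/uL.
#' @return Ratio(s); samples with a zero reference are returned as \code{NA}
#'   with a warning (unevaluable).
#' @export
ddpcr_normalize <- function(target_conc, reference_conc) {
  bad <- reference_conc <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with zero reference concentration ",
            "flagged unevaluable")
  }
  out <- ifelse(bad, NA_real_, target_conc / reference_conc)
  out
}

#' geNorm-style reference-assay stability
#'
#' For each assay j, the stability measure M_j is the mean over all other
#' assays k of the standard deviation across samples of
#' \code{log2(expr_j / expr_k)}; lower M means more stable. Also performs
#' the stepwise geNorm exclusion: the least stable assay is removed and M
#' recomputed until two remain.
#'
#' @param expr Positive matrix, assays in rows, samples in columns.
#' @return Object of class \code{"genorm"}: data frame \code{assay_id,
#'   m_value, rank} (ascending M) with attribute \code{"exclusion_order"}
#'   (assays in the order removed; the final two are the geNorm pair).
#' @export
genorm_stability <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3) stop("geNorm needs >= 3 candidate assays", call. = FALSE)
  if (any(expr <= 0)) stop("geNorm requires strictly positive values", call. = FALSE)
  m_of <- function(mat) {
    vapply(seq_len(nrow(mat)), function(j) {
      sds <- vapply(setdiff(seq_len(nrow(mat)), j), function(k) {
        stats::sd(log2(mat[j, ] / mat[k, ]))
      }, numeric(1))
      mean(sds)
    }, numeric(1))
  }
  m <- m_of(expr)
  ids <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  res <- data.frame(assay_id = ids, m_value = m, stringsAsFactors = FALSE)
  res <- res[order(res$m_value), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  # stepwise exclusion of the least stable assay
  excl <- character(0)
  cur <- expr
  while (nrow(cur) > 2) {
    mm <- m_of(cur)
    worst <- which.max(mm)
    excl <- c(excl, rownames(cur)[worst])
    cur <- cur[-worst, , drop = FALSE]
  }
  attr(res, "exclusion_order") <- c(excl, rownames(cur))
  class(res) <- c("genorm", "data.frame")
  res
}
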