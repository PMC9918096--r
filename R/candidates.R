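#' Shortlist upregulated candidate biomarkers
#'
#' Applies the validation-shortlist rule for upregulated miRNAs: adjusted
#' p below \code{padj_max}, log2 fold change at least \code{log2fc_min}
#' (inclusive), mean CPM in the injured (contrast) group at least
#' \code{cpm_min} (inclusive), and — when required — annotation as brain
#' enriched. Entries are sorted by adjusted p ascending.
#'
#' @param de A [nb_wald_test()] result (or data frame with the same columns).
#' @param cpm CPM matrix sharing miRNA ids with \code{de}.
#' @param group_samples Column names (or logical/integer index) of the
#'   samples forming the contrast (TBI) group, used for the group-mean CPM.
#' @param annotation Optional data frame with \code{mirna_id} and
#'   \code{brain_enriched}; required when \code{require_brain = TRUE}
#'   entries should be checkable. miRNAs absent from the annotation are
#'   excluded with a warning when \code{require_brain = TRUE}, otherwise
#'   kept and flagged.
#' @param log2fc_min,cpm_min,padj_max Filter thresholds.
#' @param require_brain Require brain enrichment (default TRUE).
#' @param include Character vector of miRNA ids to append manually
#'   (flagged \code{manual = TRUE}) regardless of the filters.
#' @return Data frame of class \code{"candidate_list"} with columns
#'   \code{mirna_id, log2fc, p_adj, group_cpm, brain_enriched, manual} and
#'   attribute \code{direction = "up"}.
#' @export
select_upregulated <- function(de, cpm, group_samples, annotation = NULL,
                               log2fc_min = 1.0, cpm_min = 30,
                               padj_max = 0.05, require_brain = TRUE,
                               include = character(0)) {
  cpm <- as.matrix(cpm)
  stopifnot(all(de$mirna_id %in% rownames(cpm)))
  grp_cpm <- rowMeans(cpm[de$mirna_id, group_samples, drop = FALSE])
  keep <- !is.na(de$p_adj) & de$p_adj < padj_max &
    !is.na(de$log2fc) & de$log2fc >= log2fc_min & grp_cpm >= cpm_min
  out <- data.frame(mirna_id = de$mirna_id, log2fc = de$log2fc,
                    p_adj = de$p_adj, group_cpm = grp_cpm,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (!is.null(annotation)) {
    out$brain_enriched <- annotation$brain_enriched[
      match(out$mirna_id, annotation$mirna_id)]
  } else {
    out$brain_enriched <- NA
  }
  if (require_brain) {
    missing_ann <- is.na(out$brain_enriched)
    if (any(missing_ann)) {
      warning(sum(missing_ann), " passing miRNA(s) lack brain-enrichment ",
              "annotation and were excluded")
    }
    out <- out[!missing_ann & out$brain_enriched, , drop = FALSE]
  }
  out$manual <- FALSE
  extra <- setdiff(include, out$mirna_id)
  if (length(extra)) {
    add <- data.frame(mirna_id = extra,
                      log2fc = de$log2fc[match(extra, de$mirna_id)],
                      p_adj = de$p_adj[match(extra, de$mirna_id)],
                      group_cpm = grp_cpm[match(extra, de$mirna_id)],
                      brain_enriched = if (is.null(annotation)) NA else
                        annotation$brain_enriched[match(extra, annotation$mirna_id)],
                      manual = TRUE, stringsAsFactors = FALSE)
    out <- rbind(out, add)
  }
  out <- out[order(out$manual, out$p_adj), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "direction") <- "up"
  class(out) <- c("candidate_list", "data.frame")
  out
}

#' Shortlist downregulated candidate biomarkers
#'
#' Keeps miRNAs with adjusted p below \code{padj_max}, log2 fold change at
#' most \code{log2fc_max} (inclusive), and mean CPM of at least
#' \code{cpm_min} in \emph{both} groups of the contrast.
#'
#' @param de A [nb_wald_test()] result.
#' @param cpm CPM matrix sharing miRNA ids with \code{de}.
#' @param group_a_samples,group_b_samples Sample selectors for the two
#'   contrast groups (e.g. TBI and sham).
#' @param log2fc_max,cpm_min,padj_max Filter thresholds.
#' @return Data frame of class \code{"candidate_list"} with attribute
#'   \code{direction = "down"}, sorted by adjusted p ascending.
#' @export
select_downregulated <- function(de, cpm, group_a_samples, group_b_samples,
                                 log2fc_max = -1.0, cpm_min = 100,
                                 padj_max = 0.05) {
  cpm <- as.matrix(cpm)
  stopifnot(all(de$mirna_id %in% rownames(cpm)))
  cpm_a <- rowMeans(cpm[de$mirna_id, group_a_samples, drop = FALSE])
  cpm_b <- rowMeans(cpm[de$mirna_id, group_b_samples, drop = FALSE])
  keep <- !is.na(de$p_adj) & de$p_adj < padj_max &
    !is.na(de$log2fc) & de$log2fc <= log2fc_max &
    cpm_a >= cpm_min & cpm_b >= cpm_min
  out <- data.frame(mirna_id = de$mirna_id, log2fc = de$log2fc,
                    p_adj = de$p_adj, group_cpm = cpm_a,
                    group_cpm_other = cpm_b,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$p_adj), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "direction") <- "down"
  class(out) <- c("candidate_list", "data.frame")
  out
}
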