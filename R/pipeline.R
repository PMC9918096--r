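#' Pipeline run configuration
#'
#' Collects the stage toggles and analysis thresholds of [run_pipeline()].
#' Thresholds default to the study conventions: hemolysis cut A414 0.25,
#' DE significance FDR 0.05, upregulated shortlist log2FC >= 1 with group
#' CPM >= 30, downregulated shortlist log2FC <= -1 with CPM >= 100 in both
#' groups, prevalence filter >= 1 read in >= 80\% of samples, elastic-net
#' mixing 0.5 and 10000 bootstrap resamples.
#'
#' @param sim A [sim_config()] describing the cohort to simulate.
#' @param out_dir Output directory for stage TSV/JSON files.
#' @param stages Character vector of enabled stages, a subset of
#'   \code{c("qc", "de", "select", "pcr", "roc", "panel", "lesion")}.
#' @param thresholds Named list overriding individual defaults.
#' @param seed Seed for the analysis stages (panel inner folds, bootstrap).
#' @return Object of class \code{"run_config"}.
#' @export
run_config <- function(sim = sim_config(),
                       out_dir = tempfile("mirtbi_run_"),
                       stages = c("qc", "de", "select", "pcr", "roc",
                                  "panel", "lesion"),
                       thresholds = list(), seed = 1L) {
  def <- list(a414 = 0.25, fdr = 0.05, log2fc_up = 1.0, cpm_up = 30,
              log2fc_down = -1.0, cpm_down = 100,
              prevalence_min_count = 1, prevalence_min_fraction = 0.8,
              alpha = 0.5, n_boot = 10000)
  def[names(thresholds)] <- thresholds
  structure(list(sim = sim, out_dir = out_dir, stages = stages,
                 thresholds = def, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full biomarker pipeline on a simulated cohort
#'
#' Orchestrates the stages in dependency order: cohort simulation, QC and
#' CPM normalization, negative-binomial differential expression (TBI vs
#' sham at day 2), candidate shortlisting, ddPCR quantification, per-assay
#' group statistics and ROC, elastic-net panel selection for the epilepsy
#' outcome, and T2 lesion volumetry with biomarker-lesion correlation.
#' Every stage writes its table under \code{config$out_dir} and is recorded
#' in the returned manifest; a rerun with the same configuration and seed
#' reproduces the outputs byte-identically.
#'
#' @param config A [run_config()].
#' @return Invisible manifest list: \code{files} (stage outputs),
#'   \code{seed}, \code{config_hash} (MD5 of the serialized
#'   configuration), \code{n} per stage, and package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  counts_out <- list()
  stage <- function(name, enabled = TRUE, deps = character(0), expr) {
    if (!enabled) return(NULL)
    missing_dep <- setdiff(deps, names(counts_out))
    if (length(missing_dep)) {
      stop("stage '", name, "' requires disabled/failed stage(s): ",
           paste(missing_dep, collapse = ", "), call. = FALSE)
    }
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  on <- function(s) s %in% config$stages

  cohort <- stage("simulate", TRUE, character(0), simulate_cohort(config$sim))
  counts_out$simulate <- ncol(cohort$counts)
  files["counts"] <- write_tsv(
    data.frame(mirna_id = rownames(cohort$counts), cohort$counts,
               check.names = FALSE), file.path(config$out_dir, "counts.tsv"))
  files["meta"] <- write_tsv(cohort$meta, file.path(config$out_dir, "meta.tsv"))

  d2 <- cohort$meta$timepoint == "D2"
  meta_d2 <- cohort$meta[d2, ]

  if (on("qc")) {
    qc <- stage("qc", TRUE, "simulate", {
      hem <- hemolysis_qc(meta_d2, threshold = th$a414)
      cpm <- cpm_normalize(cohort$counts)
      det <- detection_sets(cohort$counts[, d2], meta_d2$group)
      pca <- pca_summary(cpm[, d2])
      list(hem = hem, cpm = cpm, det = det, pca = pca)
    })
    counts_out$qc <- qc$hem$n_qualified
    files["qc"] <- file.path(config$out_dir, "qc.json")
    jsonlite::write_json(list(
      qualified = qc$hem$n_qualified, total = qc$hem$n_total,
      percent = qc$hem$percent, detection_sizes = as.list(qc$det$sizes),
      pca_percent_var = round(qc$pca$percent_var[1:5], 2)),
      files["qc"], auto_unbox = TRUE, digits = NA)
    files["cpm"] <- write_tsv(
      data.frame(mirna_id = rownames(qc$cpm), round(qc$cpm, 4),
                 check.names = FALSE), file.path(config$out_dir, "cpm.tsv"))
  }

  if (on("de")) {
    de <- stage("de", TRUE, c("simulate", "qc"), {
      nb_wald_test(cohort$counts[, d2], meta_d2$group, c("TBI", "sham"))
    })
    counts_out$de <- sum(de$p_adj < th$fdr, na.rm = TRUE)
    files["de"] <- write_tsv(
      within(as.data.frame(de), {
        base_mean <- round(base_mean, 4); log2fc <- round(log2fc, 4)
        se_log2fc <- round(se_log2fc, 4); wald_stat <- round(wald_stat, 4)
      }), file.path(config$out_dir, "de_TBI_vs_sham_D2.tsv"))
  }

  if (on("select")) {
    sel <- stage("select", TRUE, c("de", "qc"), {
      ann <- data.frame(mirna_id = rownames(cohort$counts),
                        brain_enriched = rownames(cohort$counts) %in%
                          cohort$truth$responsive)
      tbi_d2 <- meta_d2$sample_id[meta_d2$group == "TBI"]
      sham_d2 <- meta_d2$sample_id[meta_d2$group == "sham"]
      up <- select_upregulated(de, qc$cpm, tbi_d2, ann,
                               log2fc_min = th$log2fc_up, cpm_min = th$cpm_up,
                               padj_max = th$fdr)
      down <- select_downregulated(de, qc$cpm, tbi_d2, sham_d2,
                                   log2fc_max = th$log2fc_down,
                                   cpm_min = th$cpm_down, padj_max = th$fdr)
      list(up = up, down = down)
    })
    counts_out$select <- nrow(sel$up) + nrow(sel$down)
    files["candidates_up"] <- write_tsv(as.data.frame(sel$up),
                                        file.path(config$out_dir, "candidates_up.tsv"))
    files["candidates_down"] <- write_tsv(as.data.frame(sel$down),
                                          file.path(config$out_dir, "candidates_down.tsv"))
  }

  norm_expr <- NULL
  if (on("pcr")) {
    pcr <- stage("pcr", TRUE, "simulate", {
      qualified <- meta_d2$sample_id[hemolysis_qc(meta_d2, th$a414)$qualified]
      dd <- cohort$ddpcr[cohort$ddpcr$sample_id %in% qualified, ]
      merged <- merge_ddpcr_wells(dd)
      ref <- merged[merged$assay_id == "miR-28-3p", c("sample_id", "concentration")]
      tgt <- merged[merged$assay_id != "miR-28-3p", ]
      tgt$rel_expr <- ddpcr_normalize(
        tgt$concentration, ref$concentration[match(tgt$sample_id, ref$sample_id)])
      tgt
    })
    counts_out$pcr <- length(unique(pcr$sample_id))
    files["ddpcr"] <- write_tsv(
      within(pcr, {
        concentration <- round(concentration, 4); rel_expr <- round(rel_expr, 5)
      }), file.path(config$out_dir, "ddpcr_normalized.tsv"))
    norm_expr <- stats::xtabs(rel_expr ~ sample_id + assay_id, data = pcr)
    norm_expr <- as.matrix(unclass(norm_expr))
  }

  if (on("roc")) {
    roc_tab <- stage("roc", TRUE, c("simulate", "pcr"), {
      grp <- meta_d2$group[match(rownames(norm_expr), meta_d2$sample_id)]
      epi <- meta_d2$epilepsy[match(rownames(norm_expr), meta_d2$sample_id)]
      rows <- list()
      for (a in colnames(norm_expr)) {
        v <- norm_expr[, a]
        kw <- kruskal_wallis(v, grp)
        r_ts <- roc_curve(v[grp != "naive"], grp[grp != "naive"] == "TBI")
        r_epi <- roc_curve(v[grp == "TBI"], epi[grp == "TBI"])
        fc <- fold_change(v[grp == "TBI"], v[grp == "sham"])
        rows[[a]] <- data.frame(
          assay_id = a, kw_p = signif(kw$p_value, 4),
          fold_tbi_vs_sham = as.numeric(fc),
          auc_tbi_vs_sham = round(r_ts$auc, 3), p_tbi_vs_sham = signif(r_ts$p_value, 4),
          cutoff_tbi_vs_sham = signif(r_ts$cutoff, 4),
          sens = round(r_ts$sensitivity, 3), spec = round(r_ts$specificity, 3),
          auc_epilepsy = round(r_epi$auc, 3), p_epilepsy = signif(r_epi$p_value, 4),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
    counts_out$roc <- nrow(roc_tab)
    files["roc"] <- write_tsv(roc_tab, file.path(config$out_dir, "roc.tsv"))
  }

  if (on("panel")) {
    panel <- stage("panel", TRUE, c("simulate", "pcr"), {
      grp <- meta_d2$group[match(rownames(norm_expr), meta_d2$sample_id)]
      epi <- meta_d2$epilepsy[match(rownames(norm_expr), meta_d2$sample_id)]
      xs <- norm_expr[grp == "TBI", , drop = FALSE]
      ys <- epi[grp == "TBI"]
      pc <- panel_config(alpha = th$alpha, n_boot = th$n_boot,
                         seed = config$seed)
      suppressWarnings(panel_select(xs, ys, pc))
    })
    counts_out$panel <- length(panel$kept_features)
    files["panel"] <- file.path(config$out_dir, "panel.json")
    jsonlite::write_json(list(
      kept_features = panel$kept_features,
      empty_panel = panel$empty_panel,
      cv_auc_penalized = round(panel$cv_auc_penalized, 4),
      cv_auc = if (is.null(panel$cv_auc)) NULL else round(panel$cv_auc, 4),
      ci = if (is.null(panel$ci_low)) NULL else
        round(c(panel$ci_low, panel$ci_high), 4),
      zero_fraction = as.list(round(panel$zero_fraction, 3))),
      files["panel"], auto_unbox = TRUE, digits = NA, null = "null")
  }

  if (on("lesion")) {
    les <- stage("lesion", TRUE, c("simulate", "pcr"), {
      sham_vols <- Filter(function(v) startsWith(v$sample_id, "SHM"), cohort$t2)
      tbi_vols <- Filter(function(v) startsWith(v$sample_id, "TBI"), cohort$t2)
      band <- normal_t2_band(sham_vols)
      vols <- do.call(rbind, lapply(tbi_vols, function(v) {
        lv <- lesion_volume(v, band)
        data.frame(sample_id = v$sample_id, timepoint = v$timepoint,
                   value = lv$volume_mm3, n_abnormal = lv$n_abnormal,
                   stringsAsFactors = FALSE)
      }))
      lvl <- norm_expr
      rownames(lvl) <- meta_d2$animal_id[match(rownames(norm_expr),
                                               meta_d2$sample_id)]
      corr <- correlate_biomarker_lesion(lvl, vols)
      list(band = band, vols = vols, corr = corr)
    })
    counts_out$lesion <- nrow(les$vols)
    files["lesion_band"] <- file.path(config$out_dir, "lesion_band.json")
    jsonlite::write_json(list(lower_ms = round(les$band$lower_ms, 3),
                              upper_ms = round(les$band$upper_ms, 3),
                              n_voxels = les$band$n_voxels),
                         files["lesion_band"], auto_unbox = TRUE, digits = NA)
    files["lesion_volumes"] <- write_tsv(les$vols,
                                         file.path(config$out_dir, "lesion_volumes.tsv"))
    les$corr$rho <- round(les$corr$rho, 4)
    les$corr$p_value <- signif(les$corr$p_value, 4)
    files["lesion_correlation"] <- write_tsv(
      les$corr, file.path(config$out_dir, "lesion_correlation.tsv"))
  }

  cfg_file <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(list(sim = unclass(config$sim),
                            thresholds = th, stages = config$stages,
                            seed = config$seed),
                       cfg_file, auto_unbox = TRUE, digits = NA)
  files["config"] <- cfg_file
  manifest <- list(files = as.list(files),
                   stage_counts = counts_out,
                   seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   package_version = as.character(utils::packageVersion("mirtbi")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
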