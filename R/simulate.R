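#' Configuration for a synthetic TBI plasma-miRNA cohort
#'
#' Bundles and validates the generative parameters of [simulate_cohort()].
#' Defaults describe a lateral fluid-percussion injury study: 8 naive, 17
#' sham-operated and 90 injured (TBI) rats with an epilepsy prevalence of
#' 21/90, plasma small-RNA profiles of 565 miRNAs of which 28 are
#' brain-enriched injury-responsive with log2 fold effects spanning 1.0-7.4,
#' negative-binomial counts with dispersion 0.2 on log-normally distributed
#' library sizes (mean 1e6 reads, CV 0.4), and a sham day-9 sequencing arm
#' whose depth drops to 17\% of the others. A latent log-normal injury
#' severity (mean 1) drives both the plasma level of responsive miRNAs and
#' the T2 lesion volume; epilepsy is decoupled from severity by default
#' (\code{epilepsy_coupling = 0}), reproducing a cohort in which no miRNA
#' predicts the epilepsy outcome.
#'
#' @param n_naive,n_sham,n_tbi Animals per experimental group.
#' @param epilepsy_rate Fraction of TBI animals that develop post-traumatic
#'   epilepsy (marginal rate when \code{epilepsy_coupling = 0}).
#' @param n_mirna Number of simulated miRNAs.
#' @param n_injury_responsive Number of miRNAs whose plasma level responds to
#'   injury.
#' @param injury_log2fc Numeric vector (length \code{n_injury_responsive} or
#'   1) of log2 fold effects, TBI vs sham at day 2, at severity 1.
#' @param sham_log2fc Log2 fold effect of sham surgery vs naive at day 2
#'   (length \code{n_injury_responsive} or 1).
#' @param nb_dispersion Negative-binomial dispersion alpha
#'   (variance \code{mu + alpha mu^2}).
#' @param lib_size_mean,lib_size_cv Mean and coefficient of variation of the
#'   log-normal library sizes.
#' @param low_depth_factor Multiplier applied to sham day-9 library sizes.
#' @param lesion_coupling Cortical lesion fraction per unit severity.
#' @param epilepsy_coupling Log-odds of epilepsy per unit severity deviation;
#'   0 decouples outcome from miRNA levels.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including the seed.
#' @return An object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(n_naive = 8, n_sham = 17, n_tbi = 90,
                       epilepsy_rate = 21 / 90,
                       n_mirna = 565, n_injury_responsive = 28,
                       injury_log2fc = seq(1.0, 7.4, length.out = n_injury_responsive),
                       sham_log2fc = 0,
                       nb_dispersion = 0.2,
                       lib_size_mean = 1e6, lib_size_cv = 0.4,
                       low_depth_factor = 0.17,
                       lesion_coupling = 0.15,
                       epilepsy_coupling = 0,
                       seed = 1L) {
  stopifnot(n_naive >= 0, n_sham >= 0, n_tbi >= 0,
            n_mirna >= 1, n_injury_responsive >= 0,
            n_injury_responsive <= n_mirna,
            nb_dispersion > 0, lib_size_cv >= 0)
  if (epilepsy_rate < 0 || epilepsy_rate > 1) {
    stop("epilepsy_rate must lie in [0, 1]", call. = FALSE)
  }
  if (lib_size_mean <= 0) stop("lib_size_mean must be positive", call. = FALSE)
  if (low_depth_factor <= 0) stop("low_depth_factor must be positive", call. = FALSE)
  injury_log2fc <- rep_len(injury_log2fc, n_injury_responsive)
  sham_log2fc <- rep_len(sham_log2fc, n_injury_responsive)
  structure(list(
    n_naive = n_naive, n_sham = n_sham, n_tbi = n_tbi,
    epilepsy_rate = epilepsy_rate,
    n_mirna = n_mirna, n_injury_responsive = n_injury_responsive,
    injury_log2fc = injury_log2fc, sham_log2fc = sham_log2fc,
    nb_dispersion = nb_dispersion,
    lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
    low_depth_factor = low_depth_factor,
    lesion_coupling = lesion_coupling,
    epilepsy_coupling = epilepsy_coupling,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# ddPCR panel used by the simulator: seven brain-enriched target assays plus
# the stable endogenous reference. Fold effects (TBI vs sham at severity 1)
# and sham-level baseline concentrations (copies/uL) are fixed at magnitudes
# typical of validated injury-responsive plasma miRNAs.
ddpcr_panel <- function() {
  data.frame(
    assay_id = c("miR-434-3p", "miR-9a-3p", "miR-136-3p", "miR-323-3p",
                 "miR-124-3p", "miR-212-3p", "miR-132-3p"),
    log2fc = log2(c(4.3, 22.4, 4.4, 4.5, 18.2, 1.9, 2.2)),
    base_conc = c(30, 6, 25, 40, 8, 35, 45),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full TBI plasma-miRNA cohort with ground truth
#'
#' Draws a cohort under the generative model described in [sim_config()]:
#' per-animal latent injury severity, negative-binomial small-RNA counts at
#' day 2 and day 9, hemolysis absorbances, epilepsy outcomes and seizure
#' counts, droplet-digital-PCR readouts for a seven-target panel plus
#' reference assay, quantitative-T2 volumes at three imaging timepoints for
#' injured animals, and a 6-month histological lesion area. Injury effects
#' act at day 2 and have resolved by day 9; the sham day-9 arm is sequenced
#' at reduced depth.
#'
#' @param config A [sim_config()] object.
#' @return An object of class \code{"tbi_cohort"}: list with \code{counts}
#'   (miRNA x sample integer matrix), \code{meta} (per-sample data frame:
#'   \code{sample_id, animal_id, group, timepoint, a414, plasma_volume_ok,
#'   epilepsy, n_seizures, has_clusters}), \code{ddpcr} (per well:
#'   \code{sample_id, assay_id, well, positives, total, droplet_volume}),
#'   \code{t2} (list of \code{t2_volume} objects for sham and TBI animals at
#'   D2, D7, D21; sham volumes carry no lesion and define the normal band), \code{lesion_area_d182} (named mm^2 vector), and \code{truth}
#'   (latent severities, responsive miRNA ids, epilepsy labels).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config

  groups <- rep(c("naive", "sham", "TBI"), c(cf$n_naive, cf$n_sham, cf$n_tbi))
  n_animal <- length(groups)
  animal_id <- sprintf("%s%03d", c(naive = "NAI", sham = "SHM", TBI = "TBI")[groups],
                       stats::ave(seq_len(n_animal), groups, FUN = seq_along))

  # latent severity: log-normal, mean 1, for injured animals only
  sdlog <- 0.5
  severity <- ifelse(groups == "TBI",
                     stats::rlnorm(n_animal, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                     0)
  names(severity) <- animal_id

  # epilepsy outcome (TBI only); intercept gives the marginal rate when the
  # severity coupling is zero
  is_tbi <- groups == "TBI"
  eta <- stats::qlogis(min(max(cf$epilepsy_rate, 1e-6), 1 - 1e-6)) +
    cf$epilepsy_coupling * (severity - 1)
  epilepsy <- ifelse(is_tbi, stats::rbinom(n_animal, 1, stats::plogis(eta)) == 1, FALSE)
  n_seizures <- ifelse(epilepsy, stats::rpois(n_animal, 4) + 1L, 0L)
  # a cluster (>= 3 seizures within 24 h) requires >= 3 seizures overall
  has_clusters <- n_seizures >= 3 & stats::runif(n_animal) < 0.53

  mirna_ids <- sprintf("rno-mir-%04d", seq_len(cf$n_mirna))
  responsive <- mirna_ids[seq_len(cf$n_injury_responsive)]
  # baseline relative abundances: heavy-tailed, as in small RNA-seq profiles
  base_prop <- stats::rlnorm(cf$n_mirna, meanlog = 0, sdlog = 2)
  base_prop <- base_prop / sum(base_prop)

  timepoints <- c("D2", "D9")
  meta <- data.frame(
    sample_id = paste0(rep(animal_id, each = 2), "_", timepoints),
    animal_id = rep(animal_id, each = 2),
    group = rep(groups, each = 2),
    timepoint = rep(timepoints, n_animal),
    stringsAsFactors = FALSE
  )
  n_samp <- nrow(meta)

  lib_sdlog <- sqrt(log(1 + cf$lib_size_cv^2))
  lib <- stats::rlnorm(n_samp, meanlog = log(cf$lib_size_mean) - lib_sdlog^2 / 2,
                       sdlog = lib_sdlog)
  lib[meta$group == "sham" & meta$timepoint == "D9"] <-
    lib[meta$group == "sham" & meta$timepoint == "D9"] * cf$low_depth_factor

  # per-sample log2 effect on responsive miRNAs (day-2 injury response only)
  sev_s <- severity[meta$animal_id]
  eff <- matrix(0, cf$n_mirna, n_samp, dimnames = list(mirna_ids, meta$sample_id))
  d2 <- meta$timepoint == "D2"
  resp_idx <- seq_len(cf$n_injury_responsive)
  if (cf$n_injury_responsive > 0) {
    tbi_d2 <- d2 & meta$group == "TBI"
    sham_d2 <- d2 & meta$group == "sham"
    if (any(tbi_d2)) {
      eff[resp_idx, tbi_d2] <- outer(cf$injury_log2fc, sev_s[tbi_d2]) +
        cf$sham_log2fc
    }
    if (any(sham_d2)) eff[resp_idx, sham_d2] <- cf$sham_log2fc
  }
  mu <- t(t(base_prop * 2^eff) * lib)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cf$nb_dispersion),
                   nrow = cf$n_mirna, dimnames = dimnames(mu))

  # hemolysis and plasma volume QC variables (per sample)
  # calibrated so that ~77% of samples pass the A414 < 0.25 + volume QC and
  # qualified samples average A414 ~ 0.13 (naive slightly higher than TBI)
  a414 <- stats::rnorm(n_samp, mean = ifelse(meta$group == "naive", 0.19, 0.16),
                       sd = 0.08)
  meta$a414 <- pmax(round(a414, 3), 0.02)
  meta$plasma_volume_ok <- stats::runif(n_samp) < 0.90
  meta$epilepsy <- rep(epilepsy, each = 2)
  meta$n_seizures <- rep(n_seizures, each = 2)
  meta$has_clusters <- rep(has_clusters, each = 2)

  # ddPCR panel on day-2 plasma: 2 replicate wells per sample x assay
  panel <- ddpcr_panel()
  d2_meta <- meta[meta$timepoint == "D2", ]
  ddpcr <- vector("list", nrow(d2_meta))
  for (i in seq_len(nrow(d2_meta))) {
    g <- d2_meta$group[i]
    sev <- severity[d2_meta$animal_id[i]]
    tgt_eff <- switch(g,
      TBI = panel$log2fc * sev,
      sham = 0,
      naive = log2(0.4))           # sham surgery itself raises targets ~2.5x
    conc <- c(panel$base_conc * 2^tgt_eff, 100)   # reference at 100 copies/uL
    assays <- c(panel$assay_id, "miR-28-3p")
    rows <- lapply(seq_along(assays), function(a) {
      # abundant templates are diluted to keep lambda <= ~5 (as in practice);
      # the dilution is folded into the effective per-droplet template
      # volume, so Poisson inversion still recovers the plasma concentration
      lam <- conc[a] * 0.00085
      dil <- if (lam > 5) 2^ceiling(log2(lam / 5)) else 1
      v_eff <- 0.00085 / dil
      w1 <- simulate_droplet_readout(conc[a], 20000, v_eff)
      w2 <- simulate_droplet_readout(conc[a], 20000, v_eff)
      data.frame(sample_id = d2_meta$sample_id[i], assay_id = assays[a],
                 well = 1:2, positives = c(w1$positives, w2$positives),
                 total = 20000L, droplet_volume = v_eff,
                 stringsAsFactors = FALSE)
    })
    ddpcr[[i]] <- do.call(rbind, rows)
  }
  ddpcr <- do.call(rbind, ddpcr)

  # quantitative T2 imaging of injured animals at D2/D7/D21; the lesion
  # fraction grows with severity and follows an edema time course
  tp_scale <- c(D2 = 1, D7 = 1.2, D21 = 0.8)
  t2 <- list()
  tbi_animals <- animal_id[is_tbi]
  imaged <- animal_id[groups %in% c("sham", "TBI")]   # shams define the band
  for (a in imaged) {
    for (tp in names(tp_scale)) {
      frac <- min(0.6, cf$lesion_coupling * severity[a] * tp_scale[[tp]])
      vol <- simulate_t2_volume(c(12, 12, 6), lesion_fraction = frac,
                                voxel_volume_mm3 = 0.05)
      vol$sample_id <- a
      vol$timepoint <- tp
      t2[[paste(a, tp, sep = "_")]] <- vol
    }
  }
  lesion_area <- stats::setNames(
    round(5 * severity[tbi_animals] * stats::rlnorm(length(tbi_animals), 0, 0.15), 2),
    tbi_animals)

  structure(list(
    counts = counts,
    meta = meta,
    ddpcr = ddpcr,
    t2 = t2,
    lesion_area_d182 = lesion_area,
    truth = list(severity = severity, responsive = responsive,
                 epilepsy = stats::setNames(epilepsy, animal_id),
                 base_prop = stats::setNames(base_prop, mirna_ids)),
    config = cf
  ), class = "tbi_cohort")
}

#' @export
print.tbi_cohort <- function(x, ...) {
  g <- table(x$meta$group[x$meta$timepoint == "D2"])
  cat("Synthetic TBI plasma-miRNA cohort\n")
  cat(sprintf("  animals: %s\n",
              paste(sprintf("%d %s", as.integer(g), names(g)), collapse = ", ")))
  cat(sprintf("  counts: %d miRNAs x %d samples (D2 + D9)\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  injury-responsive miRNAs: %d; epilepsy (TBI+): %d of %d\n",
              length(x$truth$responsive), sum(x$truth$epilepsy),
              sum(x$meta$group[x$meta$timepoint == "D2"] == "TBI")))
  cat(sprintf("  ddPCR wells: %d; T2 volumes: %d; seed: %d\n",
              nrow(x$ddpcr), length(x$t2), x$config$seed))
  invisible(x)
}

#' Simulate a droplet digital PCR readout
#'
#' Partitions template molecules at \code{true_concentration} copies/uL into
#' \code{n_droplets} droplets of \code{droplet_volume} uL each; a droplet is
#' positive with probability \code{1 - exp(-concentration * volume)}
#' (Poisson occupancy).
#'
#' @param true_concentration Copies per microliter (>= 0).
#' @param n_droplets Number of accepted droplets.
#' @param droplet_volume Droplet volume in microliters.
#' @return List with \code{positives}, \code{total} and
#'   \code{droplet_volume}; invert with [droplet_to_concentration()].
#' @export
simulate_droplet_readout <- function(true_concentration, n_droplets, droplet_volume) {
  if (true_concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  stopifnot(n_droplets > 0, droplet_volume > 0)
  p <- 1 - exp(-true_concentration * droplet_volume)
  list(positives = stats::rbinom(1, n_droplets, p),
       total = as.integer(n_droplets),
       droplet_volume = droplet_volume)
}

#' Simulate a quantitative T2 map with a lesion core
#'
#' Voxels are drawn from a Gaussian distribution of normal cortical T2
#' values; a contiguous, roughly spherical core around the grid center
#' (covering \code{lesion_fraction} of the voxels) is shifted by
#' \code{lesion_shift_ms}. Defaults place the normal 2.5th-97.5th percentile
#' band at about 45-55 ms.
#'
#' @param grid_dims Integer vector of 3 positive dimensions.
#' @param lesion_fraction Fraction of voxels in the lesion core, in [0, 1].
#' @param normal_mean_ms,normal_sd_ms Normal-tissue T2 distribution (ms).
#' @param lesion_shift_ms Added to lesion-core voxels (ms); positive shifts
#'   model edema, negative ones hemorrhage.
#' @param voxel_volume_mm3 Volume of one voxel.
#' @param seed Optional seed for a self-contained reproducible volume.
#' @return Object of class \code{"t2_volume"}: list with \code{t2} (3D array,
#'   ms), \code{mask} (logical array, all \code{TRUE} here), \code{lesion}
#'   (logical array marking the planted core), \code{voxel_volume_mm3},
#'   \code{sample_id}, \code{timepoint}.
#' @export
simulate_t2_volume <- function(grid_dims, lesion_fraction,
                               normal_mean_ms = 50, normal_sd_ms = 2.551,
                               lesion_shift_ms = 30, voxel_volume_mm3 = 0.05,
                               seed = NULL) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3 || any(grid_dims < 1)) {
    stop("grid_dims must be 3 positive integers", call. = FALSE)
  }
  if (lesion_fraction < 0 || lesion_fraction > 1) {
    stop("lesion_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- prod(grid_dims)
  t2 <- array(stats::rnorm(n, normal_mean_ms, normal_sd_ms), dim = grid_dims)
  lesion <- array(FALSE, dim = grid_dims)
  k <- round(lesion_fraction * n)
  if (k > 0) {
    # contiguous core: the k voxels nearest the grid center
    ctr <- (grid_dims + 1) / 2
    coords <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                                    y = seq_len(grid_dims[2]),
                                    z = seq_len(grid_dims[3])))
    d2c <- colSums((t(coords) - ctr)^2)
    core <- order(d2c)[seq_len(k)]
    lesion[core] <- TRUE
    t2[core] <- t2[core] + lesion_shift_ms
  }
  structure(list(t2 = t2, mask = array(TRUE, dim = grid_dims), lesion = lesion,
                 voxel_volume_mm3 = voxel_volume_mm3,
                 sample_id = NA_character_, timepoint = NA_character_),
            class = "t2_volume")
}
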