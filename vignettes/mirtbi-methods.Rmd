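---
title: "Models and methods behind mirtbi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirtbi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mirtbi` packages the statistical workflow of a circulating-miRNA biomarker
study in a rat model of traumatic brain injury (TBI) and post-traumatic
epilepsy (PTE). This vignette is the package's own account of the science:
the generative model assumed by the synthetic cohorts, the analysis models
and their assumptions, every tunable parameter with its default and origin,
the numerical conventions, and the limits of what a green test establishes.

## 1. The synthetic cohort: a stated world

Real cohorts of this design are expensive (150+ animals with 6-month video-EEG
follow-up), and the raw data of any one study are not required to validate
the statistical machinery. `simulate_cohort()` therefore generates cohorts
with the structure the analysis assumes, with ground truth attached.

**Design defaults.** 8 naive, 17 sham-operated and 90 injured (TBI) animals
— the composition of a ddPCR validation cohort after quality control — with
plasma sampled at day 2 (D2) and day 9 (D9) after injury, an epilepsy
prevalence of 21/90 among TBI animals, and quantitative T2 imaging of sham
and TBI animals at D2, D7 and D21.

**Latent severity.** Each injured animal carries a latent injury severity
$s_i \sim \mathrm{LogNormal}$ with mean 1 (log-scale SD 0.5). Severity
drives everything that should co-vary in a real cohort: the plasma level of
injury-responsive miRNAs, the cortical lesion fraction (slope
`lesion_coupling`, default 0.15 per unit severity, giving a mean lesion of
~15% of the cortical grid), and optionally the epilepsy log-odds
(`epilepsy_coupling`, default 0). The paper-style null — no miRNA
difference between animals with and without epilepsy — is therefore the
default: outcomes are Bernoulli with a fixed marginal rate, independent of
miRNA levels. Setting `epilepsy_coupling > 0` turns the generator into a
power-study tool.

**Counts.** miRNA $j$ in sample $k$ is drawn
$y_{jk} \sim \mathrm{NB}(\mu_{jk}, \alpha)$ with
$\mu_{jk} = L_k \, \pi_j \, 2^{e_{jk}}$: library size $L_k$ log-normal
(mean $10^6$, CV 0.4), baseline relative abundances $\pi_j$ heavy-tailed
log-normal (log-SD 2, as in small RNA-seq profiles), dispersion
$\alpha = 0.2$ (typical bulk RNA-seq overdispersion), and log2 effect
$e_{jk}$. For the 28 injury-responsive miRNAs the D2 effect in TBI animals
is `injury_log2fc * severity` with per-miRNA effects spanning 1.0–7.4 —
the range reported for validated brain-enriched markers — and all effects
have resolved by D9. The sham-D9 arm's library sizes are multiplied by
`low_depth_factor = 0.17`, emulating a reported sequencing-depth drop to
17% in that arm.

**Hemolysis QC variables.** A414 absorbances are Normal(0.16, 0.08)
(naive animals +0.03, matching their slightly higher reported values),
and plasma volume is sufficient with probability 0.90. These two choices
are calibrated so that roughly 77% of samples qualify under the A414 < 0.25
+ volume rule and qualified samples average A414 ≈ 0.13 — the attrition and
distribution reported for a 150-animal cohort. They were fixed once, from
those two published summaries, not tuned to any test.

**ddPCR readouts.** A seven-assay target panel plus a stable reference
assay (held at 100 copies/uL) is partitioned into 20,000 droplets of
0.00085 uL; each droplet is positive with probability
$1 - e^{-cv}$ (Poisson occupancy), two replicate wells per sample x assay.
Abundant templates are "diluted" so the mean occupancy stays at or below
~5, as a laboratory would; the dilution is folded into the recorded
effective per-droplet template volume, so `droplet_to_concentration()`
still recovers the plasma concentration directly.

**T2 maps.** Normal cortical voxels are Normal(50 ms, 2.551 ms) — chosen
so the 2.5th/97.5th percentiles sit at 45 and 55 ms, the published normal
band — and a contiguous, roughly spherical core covering the lesion
fraction is shifted by +30 ms (edema-like). The lesion fraction follows an
edema time course (x1.0 at D2, x1.2 at D7, x0.8 at D21).

**What the generator does not emulate.** Compositional structure beyond
closure (no miRNA-miRNA interaction), batch and plate effects, hemolysis
leaking into miRNA levels, detection dropout structure of low-input
libraries, and the real per-miRNA abundance spectrum of plasma. A green
test therefore establishes that the *procedures* are correct and
calibrated under the assumed model — not that any particular biological
conclusion transfers.

One deliberate consequence of CPM closure is visible in the tests: when
responsive miRNAs rise with severity they consume library share, so
non-responsive miRNAs' CPM correlates slightly *negatively* with lesion
volume. The invariant checked is accordingly one-sided (no positive
coupling).

## 2. Differential expression: a simplified NB Wald test

`nb_wald_test()` is an explicit stand-in for a DESeq2 analysis, built to be
auditable rather than feature-complete: median-of-ratios size factors
(normalized to geometric mean 1; total-count fallback with a warning when
no miRNA is positive in all samples), per-miRNA method-of-moments
dispersion computed *within groups* (so true group differences do not
inflate it) with the Poisson/normalization variance component
$\mu \cdot \overline{1/s}$ subtracted and a floor of $10^{-8}$, a
two-group NB GLM with log link and log-size-factor offsets fitted by IRLS
(tolerance $10^{-8}$, 100 iterations; non-convergence yields NA p-values),
a Wald test on the group coefficient, and per-contrast BH adjustment.
There is no Cox–Reid dispersion shrinkage, no independent filtering and no
LFC shrinkage. Acceptance is via simulation-based error control (null
type-I fraction 0.05 ± 0.02 at 17-vs-90; BH-significant fraction ≈ 0) plus
a one-off cross-check against DESeq2 on a clean planted fixture, where the
two agree on effect sizes and significance calls.

## 3. The two panel procedures

Both procedures are leave-one-out on the outside, with all data-dependent
steps — standardization, feature selection, penalty tuning — strictly
inside the training fold. This is verified by a leak probe: with 200 pure
noise features, 40 samples and null labels, any leak of the held-out sample
into standardization, selection or tuning inflates the pooled CV AUC far
above chance; the test asserts the implementation stays in the null band.

**Nested LOOCV logistic discovery** (`nested_loocv_logistic`). Within each
outer fold, a stratified 5-fold inner CV scores a grid over feature
selection method (F-score filter; recursive feature elimination is
implemented and selectable), number of features (default {1, ceil(p/2),
p}), penalty type (L1 or L2) and penalty strength (6 values spanning six
decades), by pooled inner AUC; ties prefer stronger regularization, then
fewer features. The chosen configuration is refitted on the full training
fold and predicts the held-out sample. The reported CV AUC is a single ROC
over the pooled out-of-fold probabilities; feature importance is the mean
absolute standardized coefficient over outer folds (zero when unselected),
normalized to sum to 1. The defaults restrict the selection grid to the
F-score filter because RFE costs one penalized fit per eliminated feature
inside every inner fold; the procedure is unchanged, only the default grid
is smaller.

**Elastic-net panel selection** (`panel_select`). Mixing parameter
$\alpha = 0.5$ interprets "equal weighting" of LASSO and Ridge in the
standard penalty parameterization. Observations are weighted inversely to
class frequency; fitting minimizes weighted binomial deviance over a
25-point penalty grid spanning six decades. The inner stratified 5-fold CV
applies the **one-standard-error rule**: the strongest penalty whose CV
deviance is within one SE of the minimum. This is the sparsity-favoring
convention of glmnet-style tooling (and the default coefficient choice of
the MATLAB glmnet wrapper); with plain minimum-deviance selection the
procedure almost never produces exact zeros and the majority-zero exclusion
rule becomes vacuous, which contradicts the documented behavior of the
procedure on null outcomes (empty panels). A feature is excluded iff its
coefficient is exactly zero in strictly more than half of the outer folds.
Survivors are refitted by ordinary logistic regression (unweighted —
whether weights entered the published refit is unstated); the refit CV AUC
pools leave-one-out out-of-fold probabilities into a single ROC, its
p-value is the two-sided Mann–Whitney test on those pooled probabilities,
and its 95% CI is a bias-corrected and accelerated (BCa) bootstrap over
10,000 resamples of the (prediction, label) pairs.

**Class weighting as a calibration device.** With imbalanced classes
(21/69) and leave-one-out pooling, an unweighted, heavily regularized model
predicts the training-fold base rate, which anti-correlates with the
held-out label and biases the pooled null AUC far below 0.5. With
inverse-class-frequency weights the intercept-only prediction is exactly
0.5 in every fold, so ties are scored at AUC 0.5 and both procedures are
calibrated under the null (checked over replicate null cohorts). The
weighting is documented for the elastic-net procedure; the discovery
procedure adopts it as the package default for the same calibration
reason.

**BCa details.** The bias correction $z_0$ uses the fraction of bootstrap
statistics below the point estimate with ties counted half (robust when
the AUC distribution is discrete), clamped away from 0/1; the acceleration
is the jackknife skewness; resamples that lose a class are dropped. A
degenerate bootstrap distribution (e.g. AUC identically 1) collapses the
CI to the point estimate and is flagged.

## 4. Univariate statistics and ROC conventions

Group tests wrap the standard implementations (`kruskal.test`,
`wilcox.test`, `cor.test`): tie-corrected Kruskal–Wallis H with chi-square
p; Mann–Whitney exact by enumeration when both groups have n < 20 and no
ties, otherwise the tie-corrected normal approximation *without* continuity
correction so that $AUC = U/(n_1 n_2)$ holds exactly; Spearman rho with
average ranks and the asymptotic t approximation, requiring at least 5
complete pairs. The ROC is oriented "higher value = positive class" and is
never flipped, so anti-discriminating markers report AUC < 0.5. The
optimal cutpoint maximizes sensitivity + specificity over all observed
values as thresholds (rule: positive if value ≥ cutoff; direction
configurable for downregulated markers), with ties broken toward higher
specificity and then the lower cutoff. Fold changes round half-away-from-
zero to one decimal (percent mode to integers) to match the field's
reporting style; the unrounded ratio is retained as an attribute.

## 5. Shortlist rules and QC conventions

Thresholds are inclusive (≥ / ≤) because published boundary cases (e.g. a
marker at CPM 31 kept under "CPM ≥ 30", log2FC exactly 1.0) are kept.
"Low p-value" in the shortlist rules is operationalized as the same
BH-adjusted 0.05 used for DE significance; no separate cut is defined.
Hemolysis qualification is strict: A414 = 0.25 fails. QC percentages round
half-up to integers. Detection ("≥1 read in ≥1 sample of the group") is
deliberately permissive — singleton detections are known to be unreliable,
so downstream filters, not the detection rule, exclude them. PCA operates
on log2(CPM + 1) with per-miRNA centering; the transform used by published
PCA figures of this kind is typically unstated, so the choice is declared
here and pinned by tests.

## 6. Lesion volumetry

The normal T2 band is the 2.5th/97.5th percentile of pooled masked voxels
of all control volumes across all timepoints, with linear interpolation
between order statistics (R quantile type 7 — the convention is unstated
in the source literature, so it is declared and pinned by an oracle test).
Band endpoints are classified normal, matching the inequality
"45 ms ≤ T2 ≤ 55 ms" as printed. Lesion volume is the count of masked
voxels strictly outside the band times the voxel volume, with below-band
(hemorrhage-like) and above-band (edema-like) counts reported separately.
Ipsilateral restriction is expressed entirely through the cortical mask;
no registration is performed.

## 7. Reproducibility and degenerate inputs

Every stochastic function takes a seed; `simulate_cohort()` derives all of
its sub-streams from the single configured seed, and rerunning
`run_pipeline()` with the same configuration and seed reproduces stage
outputs byte-identically. Degenerate inputs have defined behavior rather
than crashes: zero-total samples name themselves in the CPM error;
saturated ddPCR wells raise a saturation error while zero-positive wells
return 0 flagged below-LOD; constant vectors make Spearman rho NA with a
warning; a constant expression matrix yields all-zero PCA variance; an
all-zero band width is flagged degenerate; perfect separation in the refit
is flagged while the pooled CV AUC is still computed.

## 8. Known limitations

The NB Wald test is anti-conservative in very small groups (method-of-
moments dispersion, no shrinkage) — its calibration is demonstrated at
17-vs-90, not at 4-vs-16. The nested discovery procedure's grid is a
declared default, not a reconstruction of any specific published grid. The
BCa interval can undercover when the refit panel separates the classes
almost perfectly (bootstrap distribution piles up at 1). Simulated cohorts
share one dispersion across miRNAs; real plasma counts show a
mean-dispersion trend. None of the acceptance checks certify agreement
with any specific study's miRNA lists or AUC values — those depend on the
real cohort.
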