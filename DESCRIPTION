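Package: mirtbi
Title: Plasma miRNA Biomarker Discovery and Validation for Traumatic Brain
    Injury Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for circulating microRNA biomarker studies in
    rodent models of traumatic brain injury and post-traumatic epilepsy.
    Covers counts-per-million normalization and quality control of small
    RNA-seq count matrices, a simplified negative-binomial Wald test for
    differential expression with Benjamini-Hochberg control, candidate
    shortlisting rules, qPCR delta-Ct and droplet digital PCR Poisson
    quantification with geNorm-style reference stability, nonparametric group
    statistics and ROC analysis with optimal cutpoints, two multivariate
    panel-selection procedures (nested leave-one-out logistic regression with
    feature selection, and elastic-net selection with majority-zero exclusion,
    unpenalized refit, pooled cross-validated AUC and BCa bootstrap
    confidence intervals), quantitative-T2 lesion volumetry, and a synthetic
    cohort generator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
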