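Package: primava
Title: Mitochondrial Priming Analytics and Apoptotic Vulnerability Assessment for Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for BH3-profiling data and integrated molecular plus
    functional biomarker modelling of glioma drug response. Computes
    mitochondrial-priming scores (BIM AUC over a peptide titration's dynamic
    range), dynamic BH3-profiling deltas and anti-apoptotic dependency calls;
    builds Integrated Molecular and Functional (IMF) and Global Molecular (GM)
    feature matrices from TP53/MDM2/MGMT status and genome-wide omics tables;
    fits relaxed elastic-net regressions under nested (leave-one-out outer,
    repeated k-fold inner) cross-validation; ranks pooled features by
    LASSO-path exit order with a permutation null; and applies the GAVA
    binary stratifier (high priming AND intact-p53-pathway status) with
    ROC/median priming thresholds, AUROC and Fisher's exact evaluation.
    A seeded synthetic-cohort generator reproduces the statistical structure
    the analysis assumes, so the whole pipeline is testable without
    controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC
Config/testthat/edition: 3
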