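Package: mirisk
Title: qPCR MicroRNA Panels for Prostate-Cancer Risk Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for small qPCR microRNA panels measured in
    urine and plasma as candidate classifiers of prostate-cancer risk.
    Covers Ct pre-processing (expression ceiling, replicate outlier
    removal, aggregation, sample quality control), endogenous-control
    assessment and geometric-mean normalization, delta-delta-Ct
    differential expression with Benjamini-Hochberg correction,
    feature-ranking stability under Monte-Carlo cross-validation, a
    primal hinge-loss linear support vector machine with ROC/AUC
    evaluation, cross-cohort validation transfer, and cross-platform
    Ct concordance.  A synthetic-cohort generator with known ground
    truth makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC
Config/testthat/edition: 3
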