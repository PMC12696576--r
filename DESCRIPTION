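Package: rcadscreen
Title: Scoring, Reliability, Copula Augmentation and Screening Models for
    the RCADS-47 Questionnaire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for machine-learning screening pipelines built on the
    Revised Child Anxiety and Depression Scale (RCADS-47): cohort input
    and validation, listwise missing-data filtering, normative T-score
    conversion and three-class labelling (Normal/Borderline/Clinical),
    Cronbach-alpha reliability analysis, consensus feature elimination
    (chi-square, Spearman, random-forest recursive feature elimination),
    Gaussian-copula augmentation of correlated ordinal item responses
    with calibrated latent correlations, SMOTE class balancing, and
    grid-searched multi-class classifier evaluation with per-class
    metrics. A synthetic-cohort generator with known ground truth makes
    the whole pipeline testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ranger,
    e1071,
    rpart,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
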