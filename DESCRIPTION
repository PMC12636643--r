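Package: csfprog
Title: Prognostic Modeling of Alzheimer's Disease from CSF Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for cerebrospinal-fluid (CSF) proteomic
    prognostics in Alzheimer's disease. Harmonizes multi-batch tandem-mass-tag
    (TMT) protein intensity matrices with an iterative median-polish-of-ratios
    procedure, removes residual technical covariates by bootstrap regression,
    extracts per-subject longitudinal rates of change with linear mixed
    models, identifies differentially abundant proteins and enriched brain
    co-expression modules via a permutation Z statistic, selects predictive
    protein panels by bootstrap-stability LASSO, evaluates them with
    random-forest classifiers over repeated stratified splits, compares
    predictor sets with a synchronized permutation test, and orders
    pre-symptomatic biomarker changes with a single-subtype event-based
    staging model. A seeded synthetic-cohort generator with full ground truth
    makes every stage testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    glmnet,
    lme4,
    ranger,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
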