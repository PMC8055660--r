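Package: falffprog
Title: Prognostic Modeling of Aphasia Therapy Outcomes from Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for predicting post-treatment
    language scores in post-stroke aphasia from resting-state BOLD fMRI. Provides
    slice-wise temporal signal-to-noise quality control, temporal-concatenation
    group spatial independent component analysis (InfoMax) with restart-stability
    assessment and dual-regression back-projection, fractional amplitude of
    low-frequency fluctuation (fALFF) feature extraction with per-subject
    sum-to-one standardization, elastic-net regression with nested leave-one-out
    cross-validation and random-forest imputation ensembles, a nonparametric
    model-assessment harness (median absolute deviation, paired Wilcoxon
    comparison against a chance model, squared Pearson correlation with
    hypothesis test, bootstrap confidence intervals), and behavioral-battery
    multicollinearity analysis (groupwise Kendall tau-b, UPGMA clustering).
    Includes a synthetic cohort generator with planted spatial sources, known
    per-subject fALFF, a multicollinear behavioral battery, and outcomes from a
    known linear model, so every stage is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    RNifti,
    randomForest,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
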