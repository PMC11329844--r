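Package: telestress
Title: Personalized Next-Week Stress Prediction from Wearable, Work-Shift,
    and Questionnaire Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a personalized machine-learning pipeline that
    predicts next-week psychological distress (K6 score of 5 or more) from
    the previous week's wearable, work-shift, and questionnaire features.
    Training data for each prediction target are restricted to a
    neighborhood cluster of the 20 participants with the nearest
    teleworking rates; per-target gradient-boosted tree classifiers are
    compared against a single pooled model, with optional decision-threshold
    adaptation on held-out cluster weeks under a true-positive-rate
    constraint. Includes a seeded synthetic cohort simulator with planted,
    teleworking-level-specific stress effects, pooled confusion-matrix and
    AUROC evaluation, and SHAP-based contribution-direction analysis
    stratified by teleworking level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
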