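Package: cierscreen
Title: Detecting Careless and Insufficient-Effort Survey Respondents with
    Tree Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes thirteen formula-defined screening predictors from a
    block of twelve consecutive Likert items plus response-time paradata
    (long-string, category-restriction, adjacent-category runs, Mahalanobis
    indices with filtered reference moments, per-item response time,
    survey-level medians), normalized so they are comparable across surveys
    with different category counts and questionnaire lengths.  Trains random
    forest and gradient boosting detectors against a directed-question
    (DQS) outcome, evaluates them with leave-one-survey-out
    cross-validation on balanced multi-survey training sets, and ships a
    synthetic multi-survey generator so the full pipeline can be exercised
    without access to real panel data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    xgboost,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
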