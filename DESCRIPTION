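Package: wordtraits
Title: Behavior-Based Linguistic Traits from Open-Vocabulary Language Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Induces latent behavior-based linguistic traits from per-user
    word usage on social media and evaluates them end to end. Builds a
    standardized user-term matrix from raw message streams, estimates a
    maximum-likelihood factor model with orthogonal (varimax, equamax) and
    oblique (promax) rotations, selects the number of factors by scree
    acceleration, and scores held-out users with regression weights.
    Includes differential language analysis with Benjamini-Hochberg false
    discovery control, a generalizability battery (non-negative matrix
    factorization of user likes, cross-validated ridge and logistic
    prediction of outcomes, demographic covariates and residualization),
    test-retest stability over calendar windows, and dropout reliability
    with Hungarian alignment of factors across refits. A synthetic corpus
    generator with planted latent traits makes every stage verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lubridate,
    Matrix,
    methods,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
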