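Package: parentlag
Title: Penalized Distributed-Lag Models for Developmentally Timed
    Parental Depression Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sensitive-period inference for life-course cohort studies of
    parental depression and adult offspring mental health. Implements
    P-spline distributed lag models (and distributed lag nonlinear
    cross-basis extensions) under proportional-odds and logistic
    likelihoods, per-occasion and cumulative adjusted odds-ratio
    contrasts with pointwise intervals, moderation Wald tests, multiple
    imputation (regularized low-rank item imputation and chained
    random-forest imputation) with Rubin-rules and D2 pooling, and a
    synthetic cohort generator with known lag-weight truths so every
    pipeline stage is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    ranger,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
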