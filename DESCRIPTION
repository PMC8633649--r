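Package: metapi
Title: Prediction Intervals and Exact Conditional Inference for
    Meta-Analysis Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for meta-epidemiological study of prediction-interval
    reporting in random-effects meta-analyses.  Back-calculates standard
    errors from reported confidence intervals, computes 95% prediction
    intervals with t quantiles on k - 2 degrees of freedom, fits
    DerSimonian-Laird random-effects models, and classifies agreement
    between confidence and prediction intervals.  Associations between
    review-level covariates and reporting are tested by exact conditional
    inference built on the noncentral hypergeometric distribution: Fisher
    exact tests (2x2 and r x 2), conditional maximum-likelihood and
    median-unbiased odds ratios, exact tail-inversion confidence limits,
    and exact logistic regression for a single continuous covariate.  A
    seeded synthetic corpus generator and a reporting pipeline with forest
    plots that display the prediction interval as a separate row complete
    the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
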