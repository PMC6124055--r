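Package: odpeval
Title: Evaluating Journal Open Data Policies and Analytic Reproducibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-research evaluations of journal open data
    policies and of analytic reproducibility. Implements interrupted
    time-series (ITS) estimation of a policy's effect on binary
    article-level outcomes via segmented logistic regression, odds-ratio
    to risk-ratio conversions (Zhang-Yu and square-root-OR) with
    delta-method inference, and an additive three-way decomposition of the
    post-policy trend. Provides Wilson continuity-corrected binomial
    confidence intervals, Sison-Glaz simultaneous multinomial confidence
    intervals, and uncorrected Pearson chi-squared tests for 2x2 tables.
    Includes a reproducibility-audit engine (percentage-error statistic,
    four-way error taxonomy, article-level outcome classification) and
    seeded synthetic generators for article corpora and audit fixtures so
    every pipeline stage can be exercised without access to the original
    coded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
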