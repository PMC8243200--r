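Package: glfsr
Title: Generalized Linear Factor Score Regression Simulation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying generalized linear factor score regression
    (GLFSR): a two-step alternative to structural equation modelling in which
    a confirmatory factor model is estimated by unweighted least squares on a
    sample correlation matrix, factor scores are computed by one of four
    scoring methods (regression, correlation-preserving, total sum, weighted
    sum), and an observed outcome is regressed on the scores with an
    identity, logit or log link. Includes a synthetic-data generator for a
    standardized two-factor, eight-indicator measurement model with uniformly
    drawn loadings, an intercept-free generalized linear model fitter using
    Fisher scoring, Monte-Carlo performance criteria (nonconvergence rate,
    relative coefficient and standard-error bias, root mean square error,
    empirical Type I error), and a meta-analysis layer with Type III sums of
    squares, partial omega-squared effect sizes and bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
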