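Package: metacfa
Title: Two-Stage Meta-Analytic Confirmatory Factor Analysis of Item
    Correlation Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pools item-level Pearson correlation matrices across primary
    studies under a fixed-effects model and fits competing confirmatory
    factor models to the pooled matrix by weighted least squares, using the
    normal-theory asymptotic covariance matrix of the pooled correlations as
    the weight matrix. Ships the standard catalogue of measurement models
    for the 20-item Toronto Alexithymia Scale (TAS-20), reconstruction of
    correlation matrices from reported factor patterns (including
    zero-imputation of loadings censored at a reporting threshold),
    exploratory factor-number criteria (Velicer's MAP test, Horn's parallel
    analysis, sample-size-adjusted BIC, sequential chi-square tests),
    bass-ackwards hierarchical component analysis, configural measurement
    invariance comparisons across study subgroups, and a seeded synthetic
    corpus generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
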