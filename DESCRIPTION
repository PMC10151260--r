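Package: homovar
Title: Tests for Homogeneity of Variance in Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A suite of two-sample and multi-sample tests for homogeneity of
    variance aimed at clinical-trial data: the variance-ratio F test,
    Ansari-Bradley test with exact null enumeration and optional Walsh-mean
    median alignment, Moses rank-like test, Miller's Jackknife test, the
    Levene family (mean, median/Brown-Forsythe, trimmed-mean, rank-based),
    Bartlett's test, Hartley's Fmax test with computed critical values,
    Cochran's C outlier-variance test, the Fligner-Killeen normal-scores
    test, and Welch's heteroscedasticity-robust ANOVA. Includes seeded
    generators for normal, Student-t and skew-normal populations with exact
    variance-ratio control, a Monte-Carlo engine estimating power and type-I
    error over sample-size grids, and a scenario-based recommender encoding
    which test to use for a given group count, distribution shape, sample
    size and anticipated variance ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
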