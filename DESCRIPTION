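Package: ordshift
Title: Response-Shift Detection and True Change for Ordinal Questionnaire Items
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Two-stage structural equation modelling for longitudinal ordinal
    (Likert-type) item responses. Stage 1 maps observed discrete responses onto
    underlying normal variables: threshold estimation, maximum-likelihood
    polychoric and tetrachoric correlations, tests of underlying bivariate
    normality, and tests of threshold invariance across measurement occasions.
    Stage 2 fits longitudinal common-factor models to the Stage-1 means and
    covariances by (diagonally) weighted least squares, detects recalibration,
    reprioritization and reconceptualization response shifts by iterative
    constraint release, and decomposes change in each item into response-shift
    and true-change components with standardized effect sizes. Includes
    chi-square, RMSEA and ECVI fit measures with noncentrality-based confidence
    intervals, a seeded generator of subject-level ordinal datasets with
    injectable response shifts, and reference tables from a published two-wave
    SF-36 study for worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    readr,
    ggplot2,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
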