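Package: ltcv
Title: Looming Test with Contrast Variation: Stimulus Scheduling and
    Psychometric Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the looming test with contrast variation (LTCV), a
    rodent defensive-behavior assay of contrast sensitivity. Builds
    Michelson-calibrated contrast levels and randomized repeated-measures
    stimulus schedules for the expanding-disk looming stimulus, models the
    scored behavioral trials (three-observer consensus, per-animal
    per-contrast response frequencies), fits the binomial logit
    contrast-response psychometric function by iteratively reweighted least
    squares, selects fixed effects bottom-up by AIC, estimates the C50
    contrast-sensitivity index per animal and per group with delta-method
    confidence intervals, runs Tukey-style pairwise contrasts and
    Bartlett-then-t group comparisons, and simulates synthetic cohorts with
    known psychometric ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    mvtnorm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    multcomp,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
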