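Package: fratiotest
Title: Resampling F-Ratio Tests and Bayesian Hypothesis Weighting for
    Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Separates fixed from random (sample-specific) effects in
    univariate and multivariate analysis of variance by a delete-d
    jackknife resampling scheme: the variance of the F statistic across
    random subject subsets, normalized as sigma^2(F)/(4<F>^2), is small
    when a fixed effect is present and is calibrated against Monte Carlo
    null distributions.  Provides the test-statistic family (teststat0,
    teststat1, teststat1R, teststat1M) with effective degrees of freedom,
    a synthetic-data generator for the repeated-measures group design,
    empirical quantiles and p-values, a comparison against the classical
    mixed-model F test, and a Bayesian hypothesis-weighting rule that
    turns test outcomes into fractional feature weights for a weighted
    linear discriminant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
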