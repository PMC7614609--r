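Package: gsepoint
Title: Unbiased and Bias-Adjusted Point Estimation for Two-Stage Group
    Sequential Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and estimation toolkit for two-stage group sequential
    trials with early stopping for efficacy. Computes O'Brien-Fleming
    stopping boundaries calibrated to an overall one-sided type I error,
    reduces cumulative two-arm binary outcome counts to the sufficient
    statistics (observed information and standardized Wald statistics),
    and provides the full suite of unconditional and conditional point
    estimators of the treatment difference: the overall and stagewise
    maximum likelihood estimates, Whitehead-style unconditional and
    conditional bias-corrected MLEs, the Rao-Blackwell UMVUE and UMVCUE,
    and the median-unbiased estimators under stagewise ordering. Also
    included are analytic conditional/unconditional bias and
    stopping-probability profiles, a simulator for the canonical joint
    distribution of the sequential test statistics, and parametric
    bootstrap standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    mvtnorm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
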