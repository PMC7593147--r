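Package: metamiss
Title: Treating and Imputing Missing Standard Deviations and Sample Sizes
    in Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how missing standard
    deviations and sample sizes affect meta-analytic grand means and
    confidence intervals. Generates mean-difference and correlation
    meta-analysis data sets from truncated distributions, deletes
    variance measures and sample sizes under MCAR, MAR, MNAR and
    effect-size-correlated scenarios, and applies fourteen treatments:
    complete-case, unweighted and sample-size-weighted analysis, single
    imputation, and nine multiple-imputation methods (chained equations
    with random-sample, linear-regression, predictive-mean-matching,
    tree, forest and Bayesian plug-ins, bootstrap
    expectation-maximization, iterative random forests, and additive
    regression with bootstrap predictive mean matching). Random-effects
    models are fitted by REML and multiply imputed estimates pooled by
    Rubin's rules; deviations from fully informed weighted analyses are
    summarized across a factorial design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    metafor,
    randomForest,
    rpart,
    splines,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
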