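Package: pstrim
Title: Weight Trimming for Propensity Score Weighting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation-based evaluation of percentile trimming of
    inverse-odds propensity score weights. Provides a scenario-based
    generator of confounded cohort data (correlated covariates, binary
    exposure from logistic models of increasing non-additivity and
    non-linearity, continuous outcome with a known treatment effect),
    four propensity score estimators (main-effects logistic regression,
    classification trees, random forests, and gradient-boosted trees
    stopped at the iteration minimising mean weighted Kolmogorov-Smirnov
    covariate imbalance), weighting-by-the-odds for the average treatment
    effect among the treated with percentile weight trimming, weighted
    least-squares effect estimation, and a Monte-Carlo metrics engine for
    absolute percent bias, standard errors, confidence interval coverage,
    and weight distribution diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    rpart,
    randomForest,
    xgboost,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
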