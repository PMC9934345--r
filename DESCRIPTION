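Package: growthcast
Title: Adult Height Forecasting from Longitudinal Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forecasts adult (age-18) stature from a child's series of annual
    height measurements using the Growth Curve Comparison method:
    cosine-similarity retrieval of the most similar reference growth curves
    followed by summation of the neighbours' mean annual height increments on
    top of the child's last observed height.  Includes the comparison
    baselines (percentile rank-preservation, linear regression, decision
    tree, extreme gradient boosting with and without a peak-height-velocity
    feature), discrete peak-height-velocity labelling and a per-year
    occurrence classifier, an evaluation harness producing per-age error
    curves, start-by-end error matrices and empirical confidence-interval
    tables, and a parametric growth-curve simulator that generates
    school-cohort-like longitudinal height data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    xgboost,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
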