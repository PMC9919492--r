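Package: stepcast
Title: Forecasting Near-Term Walking Behavior from Wearable Step Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting whether a person will take a
    walk of five minutes or more within the next three hours, from their
    prior five weeks of hourly walking states derived from minute-resolution
    wearable step counts. Includes a synthetic step-stream generator with
    circadian and weekly structure, walk-bout detection (60 steps/min for
    5 or more consecutive minutes), hourly ACTIVE/INACTIVE/MISSING state
    reduction, one-hot temporal and lag-history featurization, majority-class
    undersampling, a train/tune/test K-fold harness, adapters for six
    classifier families, random search over multilayer-perceptron
    architectures, and Matthews-correlation-based evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    Matrix,
    data.table,
    glmnet,
    e1071,
    ranger,
    rpart,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
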