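Package: neofba
Title: Functional Brain Age Prediction from Preterm Infant EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts functional brain age (FBA) of preterm infants from
    multichannel EEG. Implements a 16-channel bipolar montage over the
    neonatal 10-20 electrode set, quantitative EEG feature extraction
    (amplitude, range-EEG, inter-burst interval, spectral and fractal
    features; 86 features per channel), wrapper channel selection combining
    binary particle swarm optimisation with forward-addition and
    backward-elimination greedy search, feature selection by Pearson
    correlation filtering and recursive feature elimination with support
    vector regression, and regression model training and evaluation with
    mean absolute error in weeks. Includes a synthetic neonatal EEG cohort
    generator with postmenstrual-age-dependent burst structure so the whole
    pipeline can be exercised and tested without clinical recordings, plus
    minimal EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    randomForest,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
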