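Package: tugbalance
Title: Functional Balance Estimation from Waist-Worn Accelerometry During
    Timed Up and Go Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for surrogate assessment of functional balance in older
    adults from a waist-mounted tri-axial accelerometer worn during a 3-m
    Timed Up and Go (TUG) test. Provides tilt calibration into the
    horizontal-vertical frame, segmentation of the anterior-posterior
    "M"-shaped signal into sit-to-stand, walking and stand-to-sit phases,
    extraction of 67 clinically motivated amplitude, jerk, spatiotemporal
    and spectral features, penalized (ridge/lasso/elastic-net) regression
    of Short Form Berg Balance Scale (SFBBS) totals under a 100-iteration
    random-shuffle-split cross-validation protocol with inner 10-fold
    tuning, high/low balance-risk classification on individual SFBBS items
    with ROC/AUC analysis, and a synthetic TUG-signal and cohort simulator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
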