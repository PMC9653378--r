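Package: fingerbmi
Title: Two-Finger Intracortical BMI Decoding with ReFIT Kalman and Shallow
    Neural-Network Decoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding stack for two-degree-of-freedom finger
    brain-machine interfaces driven by binned spike-band power. Provides a
    synthetic cortical population encoder and intention-driven task simulator,
    a position-velocity Kalman filter with recalibrated feedback intention
    training (ReFIT), its steady-state gain/smoothing form, a shallow
    feed-forward neural-network velocity decoder with a learned time-feature
    layer and ReFIT retraining, a closed-loop (brain-control) experiment
    engine, and Fitts's-law performance assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
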