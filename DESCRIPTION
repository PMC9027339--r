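Package: pdgait
Title: Wearable Gait Telemetry Processing and Parkinsonian Gait
    Classification
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end processing of multichannel wearable gait telemetry
    (bilateral plantar pressure from force-sense resistors, bilateral
    Tibialis anterior / Gastrocnemius medialis surface EMG, and wrist
    acceleration) sampled at 100 Hz. Implements signal conditioning with
    block averaging and zero-phase Butterworth band-limiting, stance-phase
    segmentation from plantar pressure, biomechanical and temporal gait
    parameters (cadence, single/double support, stride-time variability),
    a 120 x 120 shifted-signal Pearson correlation coefficient matrix
    rendered as a color image, and a compact depthwise-separable
    convolutional network that classifies the rendered matrices into
    physiological versus Parkinsonian gait. A synthetic gait simulator
    with ground-truth event tables makes the whole pipeline testable
    without recorded patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    signal,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'io.R'
    'preprocess.R'
    'events.R'
    'gaitparams.R'
    'corrfeatures.R'
    'classifier.R'
    'cnn.R'
    'synthgait.R'
    'pipeline.R'
    'pdgait-package.R'
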