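Package: smartchair
Title: Sitting-Posture Classification and Invisible ECG Monitoring for Sensor Chairs
Version: 0.1.0
Authors@R: person("smartchair", "maintainers", email = "maintainers@smartchair.dev", role = c("aut", "cre"))
Description: Toolkit for smart-chair physiological monitoring. Converts
    three-point load-cell weight streams into center-of-mass features in the
    seat plane, trains and evaluates five- and seven-class sitting-posture
    classifiers (weighted k-NN, nearest centroid, SVM, Gaussian mixtures),
    and processes single-lead armrest ECG: FIR band-pass filtering,
    Hamilton-style R-peak detection, beat segmentation, and beat-level
    outlier rejection (DBSCAN, DMEAN, NCCC). Includes synthetic session and
    ECG generators with ground truth so every pipeline stage is testable
    without subject recordings.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    FNN,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
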