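Package: rotorrisk
Title: Flight-Altitude Modelling and Collision-Risk Mapping for Soaring Raptors
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for predicting where GPS-tracked soaring raptors fly
    within the rotor-swept altitude band of wind turbines (below 200 m above
    ground level). Covers cleaning of raw GPS fixes (altitude datum
    conversion, quality and daylight filtering, per-minute subsampling),
    terrain predictor derivation (slope, aspect, topographic position index,
    slope unevenness), a feedforward neural-network classifier with dropout
    trained by Adam with early stopping on validation AUC, leave-one-bird-out
    and spatial-block cross-validation, grouped permutation importance,
    ICE/partial-dependence effect curves, bagged probability maps with
    credible intervals, sensitivity-constrained binarization, and
    joint-probability and high-risk conflict maps. A synthetic-world module
    generates terrain, environmental rasters and GPS tracks with a known
    low-flight generating process so every stage is testable without
    proprietary tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
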