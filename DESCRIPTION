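Package: coilcollim
Title: Embolization-Coil Detection, Automatic Collimation and Dose Simulation for X-Ray Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for embolization-coil guided automatic
    collimation in interventional X-ray angiography. Generates seeded
    synthetic angiography phantoms (skull-like background, curled platinum
    coil absorbers, catheter distractors, collimator shutters) with
    Pascal-VOC-style ground truth; prepares raw frames (orientation
    correction, collimator cropping, standard-scaler normalization,
    fixed-resolution resize with consistent bounding-box transforms);
    detects coils with a multi-threshold dark-blob detector; plans
    collimator apertures from detections; simulates automatic
    exposure-rate control (AERC) and dose-area-product (DAP) with and
    without coil awareness; and evaluates detections with IoU, average
    precision, patient-wise k-fold splits and the Mann-Whitney U test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
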