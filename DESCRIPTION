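Package: uavpnc
Title: Plant Nitrogen Content Estimation from UAV RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Plot-level crop phenotyping from UAV digital-camera products:
    visible-band vegetation indices on normalised chromaticities, canopy
    coverage by excess-green segmentation with the maximum inter-class
    variance (Otsu) threshold, plant height from digital surface model
    differencing, and canopy volume; plant nitrogen content is then
    estimated with multiple linear regression, k-nearest-neighbour and
    random-forest models under a replication-based train/validation split
    and evaluated by R2, RMSE and NRMSE. A seeded synthetic field-scene
    generator reproduces a 48-plot potato nitrogen trial so the entire
    pipeline is testable end to end without external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    mgcv,
    randomForest,
    caret,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
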