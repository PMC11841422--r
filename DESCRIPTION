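Package: maizecount
Title: Small-Object Detection and Stand Counting for UAV Crop Imagery
Version: 0.1.0
Authors@R:
    person("Maize", "Count Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for detecting and counting crop seedlings in aerial
    (UAV) imagery where most objects are small (under 32x32 pixels). Provides
    a self-calibrated convolution block that fuses an identity branch, an
    original-scale 3x3 refinement branch and an upscaled-space calibration
    branch by elementwise multiplication; an adaptive spatial-channel feature
    fusion neck that aligns three backbone scales, concatenates them and
    applies channel-then-spatial attention; a compact CPU-trainable reference
    detector hosting both components; a tile-and-stitch counting pipeline with
    overlap de-duplication; COCO-style detection metrics including
    size-stratified average precision and stand-count regression metrics
    (R squared, RMSE, MAE, MAPE); and a seeded synthetic field-scene generator
    with LabelMe/COCO annotation interchange so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
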