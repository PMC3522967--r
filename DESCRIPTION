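Package: dielvision
Title: Diel Growth and Nutation Analysis for Growth-Chamber Time-Lapse Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis toolkit for plant growth-chamber time-lapse
    experiments run under alternating day/night illumination. Provides a
    configurable segmentation chain (preprocessing, Otsu/Kapur/Kittler
    histogram thresholding, blob detection and filtering), shape and motion
    descriptors (area, perimeter, principal-axis length and angle, centroid,
    compactness, motion vector, growth velocity), adaptive region-of-interest
    tracking of a growing and nutating organ, correction of measurement
    discontinuities at day/night illumination transitions, accumulated-growth
    and binary diel growth-pattern derivation, metric calibration from a
    circle-grid target, and a ground-truthed synthetic chamber simulator used
    to validate the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'features.R'
    'segmentation.R'
    'calibration.R'
    'io.R'
    'tracking.R'
    'timeseries.R'
    'schedule.R'
    'synthetic.R'
    'cli.R'
    'dielvision-package.R'
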