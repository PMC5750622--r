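Package: rootrose
Title: Root System Architecture Phenotyping from Four-Sided Box Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the architecture of a single gel-grown, fluorescently
    labelled plant root system from photographs of the four faces of a
    transparent growth box. Images are digitized to binary root skeletons
    (Canny edge detection with percentile hysteresis, morphological cleanup),
    opposing views are combined into XY and ZY root-density matrices, and the
    package derives the vertical depth profile (location of maximum density,
    weighted skewness and excess kurtosis) and the horizontal circular
    distribution about the hypocotyl (mean resultant length with the Rayleigh
    uniformity test, Watson's U2, mean direction, windrose sector binning, and
    overhead heatmaps). A stochastic 3D root-growth simulator renders
    synthetic box images with voxel-level ground truth, so every pipeline
    stage is testable without real photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
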