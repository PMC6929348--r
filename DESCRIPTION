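Package: texqa
Title: Texture-Based Modulation Indices and Delivery-Accuracy QA for VMAT Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the modulation degree of volumetric
    modulated arc therapy (VMAT) plans from their integrated fluence maps.
    Builds monitor-unit-weighted fluence maps from multi-leaf collimator
    (MLC) control-point sequences read from DICOM-RT Plan files or a plain
    JSON exchange format, quantizes them to 128 gray levels, computes
    gray-level co-occurrence matrices and six Haralick texture features
    (angular second moment, inverse difference moment, contrast, variance,
    correlation, entropy) at displacements 1, 5 and 10 pixels averaged over
    four directions, and correlates the resulting 18-value feature panel
    against delivery-accuracy measures: global two-dimensional gamma passing
    rates and machine-log mechanical errors (MLC position, gantry angle,
    monitor units) with Spearman rank statistics.  A synthetic arc-plan and
    delivery-log generator lets the whole feature-to-accuracy correlation
    study run end-to-end without clinical data; a command-line interface
    exposes the main operations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    png,
    pracma,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
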