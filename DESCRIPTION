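Package: nanotopo
Title: Nanometer-Precision 3D Membrane Receptor Nanotopography from
    Biplane Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intensity-ratio (dTRABI) axial localization in biplane
    single-molecule localization microscopy (SMLM/dSTORM). Builds an axial
    lookup table from a calibration scan, pairs transmitted and reflected
    channel localizations frame by frame, assigns axial coordinates from the
    normalized intensity contrast, performs fiducial-free axial drift and
    sample-tilt correction, estimates localization precision from short
    single-fluorophore tracks, and quantifies axial receptor distributions per
    region of interest with bi-Gaussian fits (z-distribution width,
    peak-to-peak distance, width difference) and population statistics. Also
    includes a fixed-width Gaussian spot fitter for raw image stacks, a
    gray-level co-occurrence homogeneity score for fluorescence images, and a
    synthetic-data generator (calibration scans, blinking membrane emitters
    with protrusions, drift, tilt, photon noise) with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
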