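Package: canopynue
Title: Canopy Nitrogen Estimation and High-NUE Phenotype Screening from
    UAV Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating rice canopy nitrogen from
    multispectral plot imagery and screening varieties for the high
    nitrogen-use-efficiency (NUE) dynamic phenotype. Covers empirical-line
    radiometric calibration of digital numbers to surface reflectance using
    ground panels of known reflectance, plot-level vegetation indices (NDVI,
    NDRE, NDGI, chlorophyll indices), quadratic and exponential regression
    models linking NDRE to canopy nitrogen (with and without leaf area index),
    growth-stage time-series assembly and a rule-based classifier for the
    high-NUE trajectory (moderate-high vegetative nitrogen, top-ranked
    reproductive nitrogen, slow post-booting decline), field yield and NUE
    trait formulas, and a synthetic field generator that emulates the full
    acquisition chain so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
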