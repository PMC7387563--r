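Package: fdti
Title: Focal Dynamic Thermal Imaging: Photothermal Simulation, Feature
    Extraction and Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Forward simulation and analysis of focal dynamic thermal
    imaging (FDTI), a label-free photothermal technique in which a
    narrow low-power laser beam heats a small tissue region and a
    thermal camera records the rise and decay of the induced surface
    temperature peak.  Provides an explicit finite-difference solver
    for the Pennes bioheat equation with an attenuated-Gaussian-beam
    volumetric heat source, builders for homogeneous tissue, porcine
    fat/muscle, pillar resolution phantoms and synthetic tumor/healthy
    cohorts, a thermal-video feature battery (peak amplitude, FWHM,
    area, volume, 2D Gaussian and Lorentzian surface fits, steady-state
    dispersion, exponential rise/decay constants), stepped-beam
    scanning versus widefield per-pixel decay mapping, and a
    statistical stage with feature ranking, control normalization and
    cross-validated quadratic discriminant classification with ROC
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    minpack.lm,
    pROC,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
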