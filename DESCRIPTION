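Package: woundvasc
Title: Label-Free Quantification of Wound Angiogenesis from Large-Scale
    Optoacoustic Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for volumetric optoacoustic (photoacoustic)
    microscopy of healing skin wounds. Converts raw depth-resolved A-scan
    streams into amplitude volumes (band-pass filtering, per-pulse energy
    correction, regridding), computes maximum-amplitude projections with
    depth indices, separates the superficial capillary plexus from deep
    cutaneous vessels via vesselness-gated surface fitting, extracts
    per-vessel morphometrics (length, diameter, tortuosity, angular
    alignment to the wound center) from skeletonized vessel masks, and
    aggregates wounds into healing-score kinetics (logistic fits),
    400-micron heat maps and radial profiles. Includes a seeded synthetic
    phantom generator with ground truth for validation, and an
    edge-spread-function resolution estimator (robust logistic fit,
    line-spread-function FWHM).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
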