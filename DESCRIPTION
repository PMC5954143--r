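Package: chromashift
Title: Fiducial-Free Chromatic Shift Registration for Multichannel
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures and corrects three-dimensional chromatic shift
    between color channels of fluorescence microscopy images without
    fiducial markers.  Seven global affine parameters (translation,
    per-axis magnification and rotation about the optical axis) are
    estimated by quadrisection phase correlation on maximum-intensity
    projections, refined by a multi-scale elastic map of local
    translations, and applied to target images with cubic
    interpolation.  Includes a synthetic-image simulator (filaments,
    beads, controlled noise), log-polar and simplex baseline
    estimators, bead-based accuracy validation, and conversion of
    parameters to real-space deviations in nanometres.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    tiff,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
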