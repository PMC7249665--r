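Package: ccdew
Title: Dual-Energy-Window Crosstalk Correction for Compton Camera Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for multi-isotope Compton camera
    imaging with dual-energy-window (DEW) scatter/crosstalk correction. Provides
    a list-mode Monte-Carlo simulator for point sources in a water phantom viewed
    by a four-layer Si/CdTe Compton camera (Klein-Nishina photon transport with
    tabulated attenuation coefficients), event selection with energy windows and
    a fluorescence veto, image reconstruction on a planar grid by Voigt-kernel
    cone backprojection and list-mode ML-EM, and DEW image subtraction with
    k-factor estimation and circular-ROI quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
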