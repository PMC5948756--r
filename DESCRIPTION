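Package: csfcount
Title: Image-Based Enumeration of Blood Cells in Cerebrospinal Fluid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for counting white and red blood cells in cerebrospinal
    fluid from paired bright-field and fluorescence micrographs of a tall
    hemocytometer-style counting chamber. Detects circular cell-like objects
    with a circle Hough transform gated by radial-symmetry score and apparent
    diameter, classifies white cells by nuclear-stain fluorescence, converts
    per-area counts into concentrations with dispersion statistics, predicts
    Stokes-law sedimentation wait times for chamber designs, and quantifies
    staining quality as a fluorescence signal-to-noise ratio. A ground-truthed
    synthetic microscopy simulator emulating the chamber's optical scene makes
    the full pipeline testable end to end without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
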