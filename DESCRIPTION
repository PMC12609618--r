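Package: gaitval
Title: Validation of Markerless Gait Analysis Against Marker-Based Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating markerless (video pose-estimation) gait
    analysis against a marker-based reference system. Provides a synthetic
    treadmill-gait generator with exact ground truth, zero-phase Butterworth
    filtering and pixel-to-metre calibration of landmark trajectories,
    kinematic detection of initial-contact and toe-off events, computation of
    spatio-temporal gait parameters (cadence, step and stance time, double
    support, step length and width, gait variability and symmetry), and
    method-agreement statistics: Lin's concordance correlation coefficient
    with heuristic bands, coefficients of variation, and Bland-Altman limits
    of agreement with the matching plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
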