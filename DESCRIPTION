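Package: ctoverrange
Title: Direct Quantification of Over-Ranging Length and Dose in Helical CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the over-ranging (overscan) length of a
    helical computed-tomography acquisition directly from real-time point
    dosimeter traces, and for expressing its dose cost as dose-length product
    (DLP). Includes a dosimeter-trace simulator that emulates a stationary
    bore dosimeter and two translating table dosimeters around a configurable
    ground-truth over-ranging model, threshold edge detection with sub-sample
    interpolation, the direct timing-based over-ranging estimator, the rival
    dose-slope extrapolation and collimation-adjusted console-reading
    estimators, a quadrature uncertainty budget, and analysis of synthetic
    computed-radiography strip images used to benchmark exposed length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
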