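Package: piledose
Title: Dose-Response and Displacement Analysis for Harbour Porpoise
    Responses to Pile-Driving Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating population-level behavioural responses of
    harbour porpoises to offshore pile driving from passive acoustic
    monitoring data. Converts echolocation click-train detections into
    detection-positive-hours series, builds diel-matched baseline and
    response windows around piling events, derives a resampled null
    distribution of proportional change in occurrence, fits probit
    random-intercept mixed models of binary response against distance or
    frequency-weighted sound exposure level, and converts the fitted
    dose-response curves into 50-percent-response thresholds and expected
    numbers of displaced individuals for comparison with radius-based
    total-displacement guidance. Includes a synthetic-data generator with
    known ground truth for validating the full inference chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
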