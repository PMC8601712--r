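Package: nightflight
Title: Flight-Altitude Dynamics from Multisensor Biologgers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the flight-altitude dynamics of nocturnally
    migrating birds recorded with multisensor biologgers. Converts 5-minute
    barometric pressure to altitude with the hypsometric formula, extracts
    flight episodes from coarse accelerometer activity scores, computes
    altitude-variation metrics (near-level fraction, mean vertical speed,
    vertical tortuosity, cruise-phase variants), detects exploratory
    to-and-fro movements, windowed maximum ascent rates and gliding or active
    descents, benchmarks the observations against a flapping-flight power
    curve and glide polar, and compares season-by-region strata with linear
    mixed models. A synthetic logger simulator with known ground truth makes
    the whole pipeline testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
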