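Package: fogatsf
Title: Wearable-Sensor Assessment of Freezing of Gait
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying freezing of gait (FOG) from body-worn
    inertial measurement units. Implements sedentary-time exclusion from a
    hip-worn gyroscope, a two-stage probabilistic FOG detector for foot-worn
    gyroscopes (zero-velocity and trembling event flags fused by a two-state
    forward probability filter), event merging, sample-wise agreement scoring
    against expert interval annotations, the percent-of-active-time-spent-
    freezing (%ATSF) outcome, and nonparametric cohort correlation analysis.
    Includes a synthetic multi-sensor cohort generator with ground-truth
    annotations and an imperfect-rater emulation so the full pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
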