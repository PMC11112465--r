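Package: stancecurves
Title: Stance-Phase Analysis of Plantar-Pressure Insole Force Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the M-shaped vertical ground-reaction-force
    curve recorded by pressure-sensing insoles during treadmill walking on
    slopes. Segments stance phases from raw 100 Hz force series by a force
    threshold with a missing-sample tolerance and duration limits, normalizes
    each stance to 100 body-weight-scaled samples by natural cubic spline
    interpolation, locates the two force maxima (Fz2, Fz4) and the midstance
    minimum (Fz3) on a Gaussian-smoothed copy through a deterministic
    disambiguation cascade, and derives nine stance-curve parameters per step.
    Per-grade summaries, normalization to percent of horizontal walking, and
    linear-regression trend statistics quantify how the curve changes with
    treadmill slope. A synthetic-gait generator produces slope-conditioned
    sessions with known ground truth so the full pipeline is testable without
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
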