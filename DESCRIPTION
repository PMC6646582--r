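Package: fatkin
Title: Individual-Based Exponential Kinetics of Neuromuscular Fatigue
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies central and peripheral neuromuscular fatigue from
    repeated maximal contractions on an individual basis. Extracts
    twitch-interpolation metrics (maximal voluntary torque, superimposed and
    potentiated resting twitches, voluntary activation) from raw isometric
    torque traces, fits the two-parameter exponential fatigue model
    (asymptote and curvature constant) to per-subject time courses of
    maximal torque, voluntary activation and evoked torque versus
    accumulated contraction time, re-expresses voluntary activation and
    evoked torque as closed-form functions of torque decline, and runs the
    cohort-level paired comparisons and parameter correlations. A synthetic
    cohort and torque-trace generator with known ground truth makes every
    stage testable without dynamometer recordings; a packaged 13-subject
    reference cohort of published fitted parameters supports desk
    reproduction of the group-level statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
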