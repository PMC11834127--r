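Package: anticept
Title: Anticipatory Smooth Eye Movements and Manual Interception
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for experiments linking anticipatory smooth
    eye movements (ASEMs) to the latency of manual interception of a moving
    target. Provides zero-phase Butterworth filtering and central-difference
    differentiation of gaze and cursor traces, saccade detection and removal
    (desaccading), blink handling, trial-level feature extraction with the
    standard exclusion rules, cumulative-Gaussian and Gaussian psychometric
    fits over signed motion coherence, paired tests, repeated-measures
    ANOVA with Holm-corrected post hocs, and BIC-based comparison of linear
    mixed-effects models coupling ASEM velocity to interception latency.
    Includes a synthetic cohort generator (eye and cursor traces with
    planted saccades, blinks and exclusion violations, plus random-dot
    motion stimulus kinematics) so every stage can be validated against
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    minpack.lm,
    signal,
    stats,
    tibble,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
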