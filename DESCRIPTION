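Package: voltdecode
Title: Synthetic Fast-Scan Cyclic Voltammetry Decoding and Perceptual
    Decision Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates fast-scan cyclic voltammetry (FSCV) measurements of
    dopamine and serotonin with known ground truth, trains the range-grid
    elastic-net decoder that maps voltammogram derivatives to analyte
    concentrations, simulates a factorial random-dot-motion task with
    two-down-one-up staircase calibration and a parametric observer, and
    runs the event-locked statistical analyses (time-point tests,
    sliding-window encoding regression, reaction-time terciles, trial-type
    transition statistics, hierarchical behavioural regressions) used to
    characterise sub-second neuromodulator signaling during perceptual
    decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    lme4,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
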