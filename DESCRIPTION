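Package: ucmforce
Title: Uncontrolled Manifold Analysis of Multi-Finger Isometric Force
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-trial uncontrolled-manifold (UCM) analysis of four-finger
    isometric force recordings: zero-phase Butterworth preprocessing, maximal
    voluntary contraction and ramp-tracking performance measures, variance
    decomposition into task-irrelevant ("good") and task-relevant ("bad")
    components via the null space of the total-force Jacobian, and the synergy
    index delta-v.  Includes a mixed-effects model-selection protocol
    (AIC for the subject random intercept, BIC among nested fixed-effect
    structures of age, group and paretic hand) and a synthetic-data generator
    producing force trials and cohorts with known ground-truth variance
    structure and age/group effects, so the full pipeline can be validated by
    parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    withr,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
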