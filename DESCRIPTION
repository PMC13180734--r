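Package: apnoeagap
Title: Apnoea Rate and EEG Brain Age Gap in Preterm Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking apnoea of prematurity to EEG-derived
    brain maturity in moderate-to-late preterm infants. Detects breaths and
    central apnoeas (inter-breath intervals longer than 15 s) from impedance
    pneumography, oxygen desaturations from pulse-oximetry traces, and
    estimates a bias-corrected brain age gap by combining a sensory-evoked
    brain-age model (neurodynamic response function slopes into a
    linear-kernel support vector regression) with a resting-state surrogate
    (30-s epoch features, 10-member ensemble, median-of-medians). Builds
    inter-breath-interval probability densities conditioned on postmenstrual
    age or brain age gap via Gaussian-weighted weighted medians, and fits the
    association statistics: linear mixed-effects models with random infant
    intercepts, partial correlations with a one-tailed bootstrap comparison,
    E-value sensitivity analysis, and the caffeine-discontinuation analyses.
    Includes a synthetic cohort generator that emulates the assumed data
    structure and provides ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
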