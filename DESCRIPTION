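Package: betabursts
Title: Transient Beta-Burst Analysis of Resting-State Sensorimotor Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transient beta-band (13-30 Hz) bursts in resting-state
    region-of-interest time courses via a data-driven amplitude threshold on
    the Hilbert envelope, and quantifies burst rate, duration, inter-burst
    interval and peak amplitude. Provides the frequency-domain counterparts
    (Welch power spectral density, relative beta power, aperiodic 1/f plus
    Gaussian-peak spectral parameterization), mixed-effects group and
    symptom-severity models with approximate Bayes-factor model comparison,
    ROC sensitivity/specificity analysis, a threshold-sweep robustness
    analysis, and a synthetic cohort generator that plants Gaussian-windowed
    beta events in 1/f noise with linked Poisson clinical scores so the whole
    pipeline is testable without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
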