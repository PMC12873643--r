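Package: attnroc
Title: ROC-Based Discriminability Analysis of Attention-Related Spiking in the Mouse Superior Colliculus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying attention-related modulation of neuronal
    spiking in head-fixed mouse visual change-detection tasks. Implements
    event-aligned spike counting and peristimulus time histograms, epoch-windowed
    ROC-area (AROC) discriminability with bootstrap confidence intervals,
    group comparison across behavioral performance levels by a random-intercept
    mixed model paired with a session-level permutation test, lick-pattern-based
    classification of behavioral sessions, signal-detection behavioral scoring,
    and velocity-threshold saccade detection from eye-position traces. Includes
    a synthetic-session generator (trial timelines, inhomogeneous-Poisson spike
    trains, lick trains, eye traces) with known ground-truth modulation so the
    whole pipeline can be exercised and validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
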