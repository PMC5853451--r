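Package: socloop
Title: Closed-Loop Auditory Stimulation of Sleep Slow Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time pipeline for phase-targeted auditory stimulation of
    sleep slow oscillations from two-channel frontal dry-EEG, together with
    the offline evaluation toolkit used to audit such a system. Includes a
    labeled synthetic sleep-EEG simulator (stage-dependent spectra, slow
    oscillations with ground-truth phase, electrode-detachment artifacts,
    movements, clock drift), the causal acquisition filter cascade, per-channel
    signal-quality gating with hysteresis channel switching, epoch-wise N3
    detection with hard safety conditions, a forgetting-factor weighted
    least-squares sinusoid fit for instantaneous slow-oscillation phase,
    a rule-based stimulation scheduler, two-device clock resynchronization,
    confusion-matrix and circular phase-accuracy metrics, and event-related
    potential delta-power statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    signal,
    data.table,
    ranger,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
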