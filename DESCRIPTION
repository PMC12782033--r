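Package: eegbench
Title: Benchmarking EEG Systems with Synthetic Multi-System Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A within-subject benchmarking pipeline for comparing EEG
    acquisition systems on classic electrophysiological effects. Generates
    stimulus sequences for five standard paradigms (resting state, SSVEP
    flicker, face perception, active and passive auditory oddball),
    synthesizes continuous multichannel EEG with known ground-truth effects
    for virtual acquisition systems differing in sampling rate, gain,
    latency, noise and trigger reliability, reads and writes BrainVision
    files, applies threshold-based artifact handling and epoching, measures
    resting-state alpha power (Berger effect), steady-state visual evoked
    potential signal-to-noise ratios, and event-related potential components
    (P100-N170 peak-to-peak, N200, P300, mismatch-negativity area under the
    curve), and runs the associated statistical battery including
    repeated-measures ANOVA with partial eta-squared, Bonferroni-adjusted
    paired t-tests, non-parametric tests, Pearson between-system
    consistency, and the bootstrap standardized measurement error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
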