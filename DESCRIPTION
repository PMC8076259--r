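Package: murisleep
Title: Sleep Architecture, Spectral and Spindle Analysis for Rodent EEG/EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rodent polysomnography under a light/dark
    schedule: vigilance-state hypnogram processing with bout consolidation,
    sleep-architecture metrics (circadian state percentages, bouts,
    transitions, sleep latencies), per-epoch normalized Welch power spectral
    density at 0.25 Hz resolution, two-threshold sleep-spindle detection on
    the cubed RMS envelope of sigma-filtered EEG, and the accompanying
    group-comparison statistics (exact Mann-Whitney U, AUC effect size with
    bootstrap confidence intervals, repeated-measures ANOVA with Sidak
    post-hoc tests). Includes a ground-truthed synthetic EEG/EMG generator
    with strain-contrast presets so every stage can be exercised without raw
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
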