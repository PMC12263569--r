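Package: s2sync
Title: Analysis Pipeline for the Speech-to-Speech Synchronization Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to score the accelerated Speech-to-Speech Synchronization
    task from raw audio. Synthesizes the accelerating /ta/ stimulus from its
    five-segment timing table, simulates whispering participants with
    controlled synchronization modes (1:1, subharmonic 1:m, free-running),
    extracts Hilbert amplitude envelopes, removes stimulus leakage with a
    Chebyshev type-II filter, detects syllable onsets and silent gaps via
    spectral flux, and computes Phase Locking Values (scalar, n:m, moving
    window with a documented legacy-bug emulation, and acceleration-based
    segmented variants). Includes a PLV-matching syllable/articulation rate
    estimator, subharmonic-synchronizer detection, and high/low/border/
    unreliable classification with printed mixture-model thresholds.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
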