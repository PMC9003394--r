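Package: dfssmvep
Title: Dual-Frequency SSmVEP Stimulus Coding and Bifold CCA Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dual-frequency steady-state motion visual evoked
    potential (SSmVEP) brain-computer interfaces. Implements binary
    stimulus frame sequencing for a monitor refresh rate, the
    dual-frequency target coding algorithm that pairs each target with a
    primary and an interleaved secondary frequency, zero-phase Chebyshev
    band-pass pre-processing and epoching of multi-channel EEG trials,
    standard canonical correlation analysis (CCA) and bifold CCA (BCCA)
    frequency recognition, Welch power spectral density utilities for
    harmonic inspection, information transfer rate (ITR) and per-class
    performance evaluation, and a ground-truthed synthetic EEG generator
    so every stage can be exercised and validated without recorded data.
    Trials are read and written as headered CSV with a JSON sidecar or as
    European Data Format (EDF) files, and a command-line interface ties
    the stages into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
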