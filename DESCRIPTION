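Package: doaflow
Title: Depth-of-Anesthesia Indices from Dominant Information Flow in
    Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies depth of anesthesia from multichannel EEG by
    measuring directed information flow with Gaussian transfer entropy
    over all source/target bipartitions of the channel set, yielding the
    indices T_max, T_min (minimum information bipartition) and T_mean.
    Includes EEG reading, filtering and windowing (EDF and CSV),
    comparator spectral indices (95% spectral edge frequency,
    band-limited spectral entropy, synch fast slow), a vector
    autoregressive simulator with analytic stationary-covariance and
    transfer-entropy oracles for validation, a three-compartment
    pharmacokinetic model of propofol with an effect compartment and
    sigmoid Emax pharmacodynamics, prediction-probability (PK) and
    Somers' D statistics, and a 2D head-map rendering of the dominant
    information flow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
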