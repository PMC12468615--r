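Package: dyscmde
Title: Multi-Domain Entropy Features and a Dynamic Synapse Classifier for EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated seizure detection in single-channel EEG from a
    nonlinear-dynamics perspective. Implements amplitude-sensitive permutation
    entropy (ASPE) and its three multi-domain extensions -- refined composite
    multiscale ASPE (RCMASPE), hierarchical wavelet-band ASPE (HASPE-DWT) and
    time-shift multiscale ASPE (TSMASPE) -- together with a structure-aware
    gated classifier ('dynamic synapse classifier', DySC) whose three parallel
    pathways mirror the grouped entropy features. Includes a seed-deterministic
    generator of EEG-like synthetic signals, readers for Bonn-style ASCII and
    EDF recordings, stratified cross-validation with the standard confusion
    matrix metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
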