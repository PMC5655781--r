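Package: eegdecode
Title: EEG Motor Decoding with Filter-Bank CSP and Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end decoding of multichannel EEG trials. Implements the
    filter-bank common spatial patterns (FBCSP) baseline with log-variance
    features, deep/shallow/hybrid/residual convolutional networks operating on
    raw EEG time series (with the evaluated design-choice toggles), trial-wise
    and cropped training including a tied neighbour-crop loss and an efficient
    dense multi-crop forward pass, and two feature-attribution methods:
    input-feature unit-output correlation maps and input-perturbation
    network-prediction correlation maps. Ships a synthetic EEG generator with
    known class-discriminative band-power structure so every stage is testable
    without external recordings, plus Wilcoxon signed-rank (with averaged-tie
    and split-zero handling) and Benjamini-Hochberg utilities, EDF/BDF readers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    withr,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
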