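Package: eegcaps
Title: Capsule-Transformer Emotion Decoding from Multi-Domain EEG Feature Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for electroencephalogram (EEG) emotion recognition from
    multi-domain feature maps. Multichannel recordings are band-filtered into
    the canonical theta, alpha, beta and gamma bands, summarised per window and
    channel by differential entropy, sample entropy and periodogram power, and
    arranged on an 8 x 9 electrode-topography grid tiled across bands into a
    3 x 16 x 18 feature tensor per time slice. A capsule network with efficient
    channel attention (ECA) and squeeze-and-excitation (SE) blocks encodes each
    slice into class capsule vectors, and a multi-head self-attention encoder
    recodes consecutive slices before softmax classification. Includes a
    synthetic EEG generator with controllable class-conditional band structure,
    adapters for DEAP- and SEED-style per-subject archives, and a stratified
    k-fold training and evaluation harness with confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
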