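Package: emdsleep
Title: Sleep Stage Classification from EEG by Empirical Mode
    Decomposition and Stacked Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated sleep-staging pipeline for single-channel
    polysomnography EEG. Reads EDF/EDF+ recordings and hypnogram
    annotations, segments them into labelled 30-second epochs, denoises
    and decomposes each epoch with a from-scratch empirical mode
    decomposition (cubic-spline envelope sifting), describes every
    intrinsic mode function with eleven time-domain statistics, learns a
    low-dimensional abstract feature pool with a greedily pretrained
    stacked autoencoder, and classifies the six Rechtschaffen-Kales
    stages (W, S1-S4, REM) with a softmax head. Includes a synthetic EEG
    generator with stage-specific spectral signatures, k-fold
    cross-validation, confusion-matrix reports, and feed-forward
    network, support-vector machine and decision-tree baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    nnet,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
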