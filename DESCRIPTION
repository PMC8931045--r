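Package: sgdal
Title: Semi-Supervised Generative and Discriminative Adversarial Learning for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding motor-imagery electroencephalography (EEG) with
    adversarially trained convolutional networks. Implements the full chain from
    multi-channel trial archives through spatial Laplacian filtering, band-pass
    filtering, resampling, baseline correction and channel-wise normalization, to
    sliding-window augmentation with majority-vote inference. Discriminators
    (Shallow ConvNet, Deep ConvNet, RSTNN variants) carry M class-score units plus
    one realness unit; generators are built by reversing a feature extractor into
    a deconvolution network with bilinear up-sampling. Training couples a
    Wasserstein critic with gradient penalty and feature matching to a supervised
    cross-entropy term, optionally exploiting unlabeled trials (semi-supervised
    mode). Learned spatial filters are transformed into forward-model activation
    patterns and rendered as topographic scalp maps. A class-conditional EEG
    simulator with a known linear forward model and mu-band event-related
    desynchronization provides ground truth for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
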