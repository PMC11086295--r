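Package: echoscope
Title: Bat Echolocation Call Synthesis, Spectrogram Features, and Compact
    Convolutional Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for classifying bat species from ultrasonic echolocation
    recordings. Generates labelled synthetic frequency-modulated pulse trains
    as a stand-in for restricted field recordings, converts audio into
    mel-scaled filter bank spectrogram images through a fixed preprocessing
    pipeline (segmentation, sample-rate relabelling, short-time Fourier
    transform, mel filter banks, cepstral coefficients, image rendering),
    and trains a compact convolutional network (about 204k parameters)
    suitable for edge deployment. Includes stratified splitting with SMOTE
    oversampling, a semi-supervised GAN variant with a dual-head
    discriminator, per-class and pairwise one-vs-one ROC evaluation, and
    utilities for streaming detection, serial payload encoding, and battery
    budgeting of field units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
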