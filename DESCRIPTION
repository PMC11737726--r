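Package: poulvoc
Title: Poultry Vocalization Classification with Wavelet Denoising and
    Mel Filter-Bank Energy Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully reproducible pipeline for classifying
    poultry vocalizations into six call classes (contentment clucks,
    hunger piping, exploratory peeping, prelaying crackles, rooster
    crowing, alarm/distress calls). Provides a seeded synthetic
    vocalization generator with configurable barn noise, multilevel
    Daubechies db1 (Haar) discrete wavelet transform denoising with
    hard/soft thresholding, short-time Fourier transform power spectra
    and log mel filter-bank energy features, a three-block 1D
    convolutional neural network classifier trained with Adam and early
    stopping, post-training int8 quantization and magnitude pruning,
    and one-vs-rest confusion-matrix metrics (precision, recall, F1,
    false positive rate) with packaged reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
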