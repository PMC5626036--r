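Package: ecgcomp
Title: Lossy ECG Compression with a Multi-Objective Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Single-channel electrocardiogram (ECG) compression built around a
    70-Nd-70 autoencoder trained under a weighted multi-objective energy that
    balances hidden-layer size, percentage root-mean-squared difference (PRD)
    and correlation coefficient (CC). Includes an undecimated (a-trous) dyadic
    wavelet transform for baseline-wander removal and denoising, R-peak
    detection from wavelet modulus maximum-minimum zero-crossings, fixed-length
    beat segmentation with two-rate downsampling to 70 samples per beat,
    discrete hidden-size selection, dynamic-time-warping beat matching, a
    JSON compressed-record container, and a seeded synthetic ECG generator so
    the whole pipeline is testable without real recordings.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
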