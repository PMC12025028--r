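Package: emgmixer
Title: Granular Surface-EMG Gesture Recognition with ConvMixer Feature Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for recognising pouring gestures from multichannel surface
    electromyography (sEMG). Provides a protocol-faithful synthetic sEMG
    generator, powerline-notch and Butterworth preprocessing, overlapping
    window segmentation, classic time-domain features (RMS, VAR, ZC, WL), a
    granular (coarse-to-fine) gesture label system with probability
    coarsening, a from-scratch ConvMixer classifier with handcrafted-feature
    fusion, one-vs-rest evaluation metrics, and feature-only SVM, random
    forest and LDA baselines, orchestrated as a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
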