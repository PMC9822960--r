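Package: lightmyo
Title: Lightmyography and Electromyography Gesture and Force Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for optical muscle-machine
    interfaces. Generates seeded synthetic recordings from a five-module
    lightmyography (LMG) armband with time-multiplexed green/infrared LEDs,
    five-channel bipolar surface EMG, and grip-force ramps; demultiplexes,
    filters and windows the signals; extracts the eight classical EMG
    time-domain features; and decodes hand gestures and grasp forces with
    three model families (random forests, convolutional networks, and a
    temporal multi-channel vision transformer implemented natively on BLAS
    matrix operations). Evaluation covers repetition-blocked cross-validation,
    NMSE and Pearson trajectory agreement, a photodiode/LED performance
    index, and one-way ANOVA comparison of the two sensing modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    data.table,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
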