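Package: mmhar
Title: Multimodal Human Locomotion Decoding from Inertial, Ambient and Vision Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular pipeline for decoding human locomotion activities from
    synchronized multimodal recordings: quaternion-based filtration of inertial
    measurement unit (IMU) streams, background-subtraction skeleton modelling of
    video frames, overlapped time-window and event-based segmentation, six
    descriptor families (Gaussian Markov random field statistics, a
    multisynchrosqueezing spatial-temporal frequency graph, an ambient sensor
    graph, thermal motion maps, generalized-Gaussian saliency, skeleton
    orientation angles and spider local image features), a Gaussian mixture
    codebook with Gaussian mixture regression encoding, and an Elman recurrent
    network classifier evaluated by recording-level cross-validation. Includes a
    seeded synthetic multimodal recording generator so the full pipeline is
    exercisable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    png,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
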