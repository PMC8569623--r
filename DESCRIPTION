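Package: semgesture
Title: Dynamic Hand-Gesture Recognition from Surface EMG and Accelerometer
    Signals with a Multi-Stream Residual ConvLSTM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding dynamic hand movements from multichannel
    surface electromyography (sEMG) fused with tri-axial accelerometer
    traces. Covers the full recognition pipeline: energy-threshold active
    segment detection, power-line comb filtering, coif5 wavelet denoising
    with SURE hard thresholding, sEMG image and time/frequency feature
    image construction (MAV, FR, MDF, MNP), mutual-information feature
    ranking, and a multi-stream residual network (squeeze-and-excitation
    residual units with channel-shuffled grouped pointwise convolution)
    fused over time by a Variant ConvLSTM whose gates operate on globally
    pooled channel descriptors. Includes a seeded synthetic sEMG +
    accelerometer generator emulating a rest/action acquisition protocol,
    a reproducible training loop, evaluation metrics, and the four-way
    ablation (single vs. multi stream, raw vs. feature images, with and
    without accelerometer fusion).
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
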