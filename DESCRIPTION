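Package: neopulse
Title: Motion-Robust Camera-Based Heart Rate Estimation for Neonates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Remote photoplethysmography (rPPG) pipeline for estimating the
    heart rate of hospitalized newborns from RGB video in the presence of
    motion artifacts. The frame is segmented to the facial skin region by
    HSV-interval thresholding with morphological smoothing, divided into an
    equal grid of patches, and each patch video is processed by Eulerian
    video magnification (Laplacian pyramid decomposition, ideal temporal
    bandpass over the neonatal heart-rate band, amplification and
    recombination). Per-patch blood-volume-pulse traces are obtained by
    spatial averaging of the green channel, converted to per-second heart
    rates by sliding-window peak counting, and fused by histogram majority
    voting. Includes agreement metrics (MAE, MRE, RMSE, SD of error,
    Bland-Altman limits of agreement), lossless uncompressed AVI input and
    output, and a synthetic-video generator with known ground-truth beat
    times for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
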