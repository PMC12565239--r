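Package: eogread
Title: Reading Electrooculography Simulation, Oculomotor Feature
    Extraction, and Scalogram-Based CNN Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-channel electrooculography (EOG)
    recorded while children read text. Simulates reading EOG with known
    ground-truth ocular events (fixation/saccade staircases, regressive
    saccades, line-return sweeps, blinks), applies the standard biosignal
    preprocessing chain (Butterworth band-pass, notch, baseline
    correction, fixed-length framing), extracts oculomotor reading
    features (reading time, blink rate, regression rate, signal energy)
    with group-comparison reports, converts signal frames into continuous
    wavelet transform energy scalogram images, and trains a compact
    four-block convolutional network on those images with stratified
    k-fold cross-validation and confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
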