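Package: ecaptools
Title: Evoked Compound Action Potential Analysis for Circumferential
    Spinal Cord Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Signal-analysis chain for multichannel epidural recordings made
    with electrode arrays wrapped around the spinal cord circumference.
    Implements stationary-wavelet denoising with the universal hard
    threshold, evoked compound action potential (ECAP) detection,
    circumferential topographic mapping and hotspot localization,
    k-nearest-neighbour classification of evoked-potential sources, a
    closed-loop injury-bypass trigger simulation with latency statistics,
    and spinal-cord circularity morphometry. A synthetic-session generator
    with ground truth supports recovery testing without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    uwot,
    withr
Config/testthat/edition: 3
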