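Package: radarposture
Title: Sleep-Posture Classification from FMCW Radar Motion Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for contactless sleep-posture recognition with a
    single-antenna frequency-modulated continuous-wave (FMCW) millimetre-wave
    radar. Includes a physics-based synthetic bed-scene simulator (quasi-periodic
    chest displacement from respiration and heartbeat, static clutter, DC offset,
    noise), intermediate-frequency signal preprocessing by consecutive mean
    subtraction, per-chirp range Fourier transforms, sliding-window standard
    deviation motion features with optimal range-bin window selection, time-shift,
    range-shift and mix-up augmentation, and a two-stage residual-convolution plus
    temporal-convolution-network classifier (ResTCN) trained with AdamW, evaluated
    subject-wise with confusion-matrix metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
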