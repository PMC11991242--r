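Package: vitalchirp
Title: Vital-Activity Detection from FMCW Radar Chirps with
    Hardware-Constrained Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-channel Frequency-Modulated Continuous-Wave
    (FMCW) radar in-phase/quadrature chirp recordings of breathing humans
    and confusable moving distractors, summarises them with a
    differential-chirp mean-energy motion descriptor, and classifies
    descriptor sequences with a compact stacked gated-recurrent-unit (GRU)
    network trained under analog-VLSI constraints: a periodic quantization
    loss pulling weights onto a 4-bit-plus-sign codebook, per-neuron affine
    weight renormalization that diversifies effective weight sets, and
    fan-in-limited dot-product decomposition. Includes detection metrics,
    a seeded hyperparameter grid runner, lossless persistence for
    recordings and (quantized) model checkpoints, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
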