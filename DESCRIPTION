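Package: srnn
Title: Successor Representation Learning in Recurrent Networks with Local Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a recurrent network model of hippocampal predictive maps
    that learns the successor representation (SR) through a local, biologically
    plausible plasticity rule combining spike-timing-dependent potentiation with
    a decorrelative anti-Hebbian normalization, modulated by an adaptive
    (metaplastic) per-neuron learning rate. Provides discrete-state environments
    (circular track, square arena) with random-walk simulators and a synthetic
    foraging-trajectory generator, feature encodings from one-hot to dense
    spatially correlated inputs, steady-state retrieval dynamics (closed-form,
    truncated, and tanh-iterative), generalized plasticity-kernel learning with
    a derivative-free parameter search, feedforward temporal-difference and
    independent-normalization baselines, evaluation metrics (matrix recovery
    error, TD loss, spectral stability, closed-form weight oracle), and spatial
    coding analyses (rate maps, permutation-test place-field detection,
    field-statistic distributions, KL comparison, peak-shift analysis).
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
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
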