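Package: chaonas
Title: Multi-Chaotic Human-Evolution Optimization and Hardware-Aware
    Neural Architecture Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the human evolutionary optimization algorithm (HEOA)
    and a multi-chaotic variant in which pseudo-random diversity sources are
    replaced by one of six chaotic maps (logistic, tent, sine, Henon,
    Chebyshev, circle), together with Lyapunov-exponent estimation, a
    classic benchmark-function harness with win-table statistics, and a
    hardware-aware neural-architecture-search layer: a 28-gene genome codec
    for compact convolutional networks, deterministic parameter counting, an
    FPGA-style parameter-budget fitness gate, a deterministic surrogate
    evaluator, a stratified data splitter, and a synthetic single-channel
    image generator for end-to-end smoke testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
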