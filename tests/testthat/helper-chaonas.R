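# Small shared fixtures for fast tests.

tiny_config <- function(...) {
  heoa_config(pop_size = 10, max_iters = 40, seed = 11, ...)
}

all_maps <- c("logistic", "tent", "sine", "henon", "chebyshev", "circle")
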