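# Named random-number streams.
#
# Every stochastic component draws from its own stream, derived from the
# single user-facing seed plus a stream label. Adding draws in one component
# therefore never perturbs another, which is what makes single-seed runs
# reproducible across versions.

#' Derive a child seed from a master seed and a stream label
#'
#' Deterministic, label-sensitive mixing kept inside the 32-bit signed
#' integer range so it is always a legal `set.seed()` argument.
#'
#' @param seed integer master seed.
#' @param label character stream name.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 1048573 * 2039 + h) %% 2147483629 + 1)
}

# A stream is an environment holding a private .Random.seed state; draws swap
# the state in, evaluate, and swap it back out, leaving the global RNG as it
# was found.
new_rng_stream <- function(seed, label) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(derive_seed(seed, label))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  env
}

stream_eval <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

stream_runif <- function(stream, n, min = 0, max = 1) {
  stream_eval(stream, stats::runif(n, min, max))
}

stream_rnorm <- function(stream, n) {
  stream_eval(stream, stats::rnorm(n))
}

stream_sample <- function(stream, x) {
  stream_eval(stream, sample(x))
}
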