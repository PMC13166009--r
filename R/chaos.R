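# Chaotic generators.
#
# Six discrete-time chaotic maps serve as structured randomness sources for
# the optimizer: logistic, tent (breakpoint 0.7), sine, Henon (2-D),
# Chebyshev (degree 4) and circle (Omega = 0.5, K = 1.5). Each is exposed as
# a one-step transition, a normalized orbit generator, and a
# Lyapunov-exponent estimator.

CHAOS_MAPS <- c("logistic", "tent", "sine", "henon", "chebyshev", "circle")

#' Chaotic map state
#'
#' Construct the state of one chaotic generator: the current primary value
#' `x` in the map's native range, the Henon companion value `y` (0 for 1-D
#' maps), and the fixed map constants.
#'
#' Native ranges are `[0, 1]` for the logistic, tent, sine and circle maps,
#' `[-1, 1]` for the Chebyshev map, and the bounded attractor box
#' `[-1.5, 1.5] x [-0.45, 0.45]` for the Henon map.
#'
#' @param map_id one of `"logistic"`, `"tent"`, `"sine"`, `"henon"`,
#'   `"chebyshev"`, `"circle"`.
#' @param x current primary value (native range of the map).
#' @param y Henon companion value; ignored for 1-D maps.
#' @return an object of class `chaotic_state`.
#' @examples
#' s <- chaotic_state("logistic", x = 0.25)
#' chaos_step(s)$x # 0.75
#' @export
chaotic_state <- function(map_id, x, y = 0) {
  map_id <- match.arg(map_id, CHAOS_MAPS)
  check_native_range(map_id, x)
  params <- switch(map_id,
    logistic  = list(alpha = 4),
    tent      = list(breakpoint = 0.7),
    sine      = list(),
    henon     = list(a = 1.4, b = 0.3),
    chebyshev = list(degree = 4),
    circle    = list(Omega = 0.5, K = 1.5)
  )
  structure(list(map_id = map_id, x = x, y = y, params = params),
            class = "chaotic_state")
}

check_native_range <- function(map_id, x) {
  ok <- switch(map_id,
    chebyshev = x >= -1 && x <= 1,
    henon     = is.finite(x),
    x >= 0 && x <= 1
  )
  if (!isTRUE(ok)) {
    stop(sprintf("value %.6g outside the native range of the %s map", x, map_id),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Advance a chaotic state by one step
#'
#' Applies the named map once: logistic \eqn{x' = 4x(1-x)}; tent with
#' breakpoint 0.7 (\eqn{x/0.7} below, \eqn{(1-x)/0.3} at or above); sine
#' \eqn{\sin(\pi x)}; Henon \eqn{x' = 1 - 1.4x^2 + y,\ y' = 0.3x};
#' Chebyshev \eqn{\cos(4 \arccos x)}; circle
#' \eqn{x + 0.5 - (1.5/2\pi)\sin(2\pi x) \bmod 1}.
#'
#' @param state a [chaotic_state()].
#' @return the one-step image, as a new `chaotic_state`.
#' @export
chaos_step <- function(state) {
  stopifnot(inherits(state, "chaotic_state"))
  check_native_range(state$map_id, state$x)
  x <- state$x
  out <- state
  switch(state$map_id,
    logistic = {
      out$x <- 4 * x * (1 - x)
    },
    tent = {
      out$x <- if (x < 0.7) x / 0.7 else (1 - x) / 0.3
    },
    sine = {
      out$x <- sin(pi * x)
    },
    henon = {
      out$x <- 1 - 1.4 * x^2 + state$y
      out$y <- 0.3 * x
    },
    chebyshev = {
      out$x <- cos(4 * acos(x))
    },
    circle = {
      out$x <- (x + 0.5 - (1.5 / (2 * pi)) * sin(2 * pi * x)) %% 1
    }
  )
  out
}

#' Normalize a chaotic state onto the unit interval
#'
#' The optimizer consumes chaotic values in `[0, 1]`. Maps that already live
#' there pass through unchanged; the Chebyshev value is mapped affinely from
#' `[-1, 1]`, and the Henon primary value from the attractor x-range
#' `[-1.5, 1.5]` (clipped, since excursions slightly beyond the nominal box
#' can occur during the transient).
#'
#' @param state a [chaotic_state()].
#' @return a value in `[0, 1]`.
#' @export
chaos_unit_value <- function(state) {
  stopifnot(inherits(state, "chaotic_state"))
  switch(state$map_id,
    chebyshev = (state$x + 1) / 2,
    henon     = min(max((state$x + 1.5) / 3, 0), 1),
    state$x
  )
}

# Perturb values absorbed by fixed points (0 and 1 for unit-interval maps,
# +/-1 for Chebyshev). Without the guard a tent or logistic orbit landing
# exactly on 0 stays there forever.
guard_absorption <- function(map_id, x, eps = 1e-12, nudge = 1e-6) {
  fixed <- switch(map_id,
    chebyshev = c(-1, 1),
    henon     = numeric(0),
    c(0, 1)
  )
  for (f in fixed) {
    if (abs(x - f) < eps) x <- f + if (f > 0) -nudge else nudge
  }
  x
}

chaos_x0 <- function(map_id, seed) {
  x0 <- stream_runif(new_rng_stream(seed, paste0("chaos-x0-", map_id)), 1,
                     0.05, 0.95)
  # avoid starting on a map fixed point (e.g. logistic 0.75, tent 1/1.3)
  s <- chaotic_state(map_id, x0)
  if (abs(chaos_step(s)$x - x0) < 1e-9) x0 <- x0 + 1e-4
  x0
}

#' Generate a normalized chaotic orbit
#'
#' Iterates the named map from a seeded starting point drawn uniformly in
#' (0.05, 0.95), discards a transient, and returns `n` values normalized to
#' the unit interval via [chaos_unit_value()]. Deterministic given
#' `(map_id, seed)`.
#'
#' @param map_id map name (see [chaotic_state()]).
#' @param n number of values to return (at least 1).
#' @param seed integer seed controlling the starting point.
#' @param transient number of initial steps discarded (default 100) so the
#'   orbit starts on the attractor.
#' @return numeric vector of `n` values in `[0, 1]`.
#' @examples
#' head(chaos_orbit("tent", 5, seed = 1))
#' @export
chaos_orbit <- function(map_id, n, seed, transient = 100) {
  map_id <- match.arg(map_id, CHAOS_MAPS)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  st <- chaos_orbit_raw(map_id, n, seed, transient)
  if (map_id == "chebyshev") return((st$x + 1) / 2)
  if (map_id == "henon") return(pmin(pmax((st$x + 1.5) / 3, 0), 1))
  st$x
}

# Raw native-range orbit; returns list(x, y) vectors of length n.
chaos_orbit_raw <- function(map_id, n, seed, transient = 100) {
  x <- chaos_x0(map_id, seed)
  y <- 0
  a <- 1.4; b <- 0.3; k_over_2pi <- 1.5 / (2 * pi)
  total <- n + transient
  xs <- numeric(n)
  ys <- numeric(n)
  for (i in seq_len(total)) {
    x <- guard_absorption(map_id, x)
    if (map_id == "logistic") {
      x <- 4 * x * (1 - x)
    } else if (map_id == "tent") {
      x <- if (x < 0.7) x / 0.7 else (1 - x) / 0.3
    } else if (map_id == "sine") {
      x <- sin(pi * x)
    } else if (map_id == "henon") {
      xn <- 1 - a * x^2 + y
      y <- b * x
      x <- xn
    } else if (map_id == "chebyshev") {
      x <- cos(4 * acos(x))
    } else {
      x <- (x + 0.5 - k_over_2pi * sin(2 * pi * x)) %% 1
    }
    if (i > transient) {
      xs[i - transient] <- x
      ys[i - transient] <- y
    }
  }
  list(x = xs, y = ys)
}

# Sequential chaotic draw stream used inside the optimizer: state advances
# one map step per requested value.
chaos_stream <- function(map_id, seed, transient = 100) {
  env <- new.env(parent = emptyenv())
  env$map_id <- match.arg(map_id, CHAOS_MAPS)
  env$x <- chaos_x0(map_id, seed)
  env$y <- 0
  env$draw <- function(n) {
    out <- chaos_advance(env, n)
    out
  }
  chaos_advance(env, transient)
  env
}

chaos_advance <- function(env, n) {
  map_id <- env$map_id
  x <- env$x; y <- env$y
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- guard_absorption(map_id, x)
    if (map_id == "logistic") {
      x <- 4 * x * (1 - x)
    } else if (map_id == "tent") {
      x <- if (x < 0.7) x / 0.7 else (1 - x) / 0.3
    } else if (map_id == "sine") {
      x <- sin(pi * x)
    } else if (map_id == "henon") {
      xn <- 1 - 1.4 * x^2 + y
      y <- 0.3 * x
      x <- xn
    } else if (map_id == "chebyshev") {
      x <- cos(4 * acos(x))
    } else {
      x <- (x + 0.5 - (1.5 / (2 * pi)) * sin(2 * pi * x)) %% 1
    }
    out[i] <- if (map_id == "chebyshev") (x + 1) / 2
      else if (map_id == "henon") min(max((x + 1.5) / 3, 0), 1)
      else x
  }
  env$x <- x; env$y <- y
  out
}

#' Estimate the Lyapunov exponent of a chaotic map
#'
#' For the 1-D maps the exponent is the long-run average of
#' \eqn{\ln|f'(x_n)|} along a post-transient orbit (tent: branch slopes
#' \eqn{1/0.7} and \eqn{1/0.3}; steps landing exactly on the breakpoint,
#' where the derivative is undefined, are skipped). For the 2-D Henon map
#' the largest exponent is computed by Benettin tangent-vector iteration:
#' a tangent vector is propagated through the Jacobian and renormalized at
#' every step, accumulating log norms.
#'
#' Closed-form reference values: logistic \eqn{\ln 2 \approx 0.693}, tent
#' \eqn{-0.7\ln 0.7 - 0.3\ln 0.3 \approx 0.611}, Chebyshev
#' \eqn{\ln 4 \approx 1.386}; the Henon attractor's accepted largest
#' exponent is about 0.419.
#'
#' @param map_id map name.
#' @param n orbit length used for averaging (default 1e6; at least 1e4).
#' @param seed integer seed for the starting point.
#' @param transient discarded initial steps.
#' @return the estimated exponent in nats per iteration.
#' @export
chaos_lyapunov <- function(map_id, n = 1e6, seed = 1, transient = 100) {
  map_id <- match.arg(map_id, CHAOS_MAPS)
  if (n < 1e4) stop("n must be at least 1e4 for a stable estimate", call. = FALSE)
  if (map_id == "henon") return(lyapunov_henon(n, seed, transient))
  st <- chaos_orbit_raw(map_id, n, seed, transient)
  # derivative is evaluated at the pre-image of each step
  x <- c(chaos_x0_post_transient(map_id, seed, transient), st$x[-n])
  d <- switch(map_id,
    logistic  = abs(4 - 8 * x),
    tent      = ifelse(x < 0.7, 1 / 0.7, 1 / 0.3),
    sine      = abs(pi * cos(pi * x)),
    chebyshev = abs(4 * sin(4 * acos(x)) / sqrt(pmax(1 - x^2, .Machine$double.eps))),
    circle    = abs(1 - 1.5 * cos(2 * pi * x))
  )
  if (map_id == "tent") d[abs(x - 0.7) < 1e-15] <- NA
  mean(log(d[d > 0]), na.rm = TRUE)
}

chaos_x0_post_transient <- function(map_id, seed, transient) {
  chaos_orbit_raw(map_id, 1, seed, transient - 1)$x
}

lyapunov_henon <- function(n, seed, transient) {
  x <- chaos_x0("henon", seed)
  y <- 0
  for (i in seq_len(transient)) {
    xn <- 1 - 1.4 * x^2 + y; y <- 0.3 * x; x <- xn
  }
  v1 <- 1; v2 <- 0
  acc <- 0
  for (i in seq_len(n)) {
    # tangent vector through the Jacobian [[-2.8 x, 1], [0.3, 0]]
    w1 <- -2.8 * x * v1 + v2
    w2 <- 0.3 * v1
    nrm <- sqrt(w1 * w1 + w2 * w2)
    acc <- acc + log(nrm)
    v1 <- w1 / nrm; v2 <- w2 / nrm
    xn <- 1 - 1.4 * x^2 + y; y <- 0.3 * x; x <- xn
  }
  acc / n
}

#' Lyapunov exponents of all six maps
#'
#' Convenience wrapper returning a tibble of estimates, one row per map.
#'
#' @inheritParams chaos_lyapunov
#' @return a tibble with columns `map`, `lyapunov`.
#' @export
chaos_lyapunov_table <- function(n = 1e6, seed = 1) {
  tibble::tibble(
    map = CHAOS_MAPS,
    lyapunov = vapply(CHAOS_MAPS, chaos_lyapunov, numeric(1), n = n, seed = seed)
  )
}
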