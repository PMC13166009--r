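# Human-evolution optimizer with pluggable chaotic randomness.
#
# The algorithm runs in two phases over T iterations. During the first
# quarter (exploration) every individual takes Levy-flight steps around the
# global best with a quantized jump toward/away from the population mean.
# Afterwards (development) the population is ranked by fitness into leaders
# (top 40%), explorers (40-80%), followers (80-90%) and losers (90-100%),
# each with its own update rule. The multi-chaotic variant replaces the
# uniform random draws that steer these moves with values from a chaotic
# map, and re-seeds the worst fifth of the population from the map whenever
# normalized positional diversity collapses below a threshold.

#' Optimizer configuration
#'
#' @param pop_size population size N (default 30; at least 5).
#' @param max_iters iteration budget T (default 500; at least 4).
#' @param map chaotic map used for initialization, in-loop chaotic draws and
#'   diversity reinitialization (default `"tent"`).
#' @param seed integer master seed; every internal stream derives from it.
#' @param assessment leader situation-assessment threshold A (default 0.6).
#' @param jump_divisor jump quantization divisor \eqn{\delta} in
#'   `[100, 2000]` (default 1000); the jump unit is
#'   \eqn{f_{jump} = (lb - ub)/\delta}.
#' @param levy_gamma Levy stability index (default 1.5).
#' @param diversity_threshold normalized-diversity level below which partial
#'   reinitialization triggers (default 0.01).
#' @param reinit_fraction fraction of worst individuals replaced on a
#'   diversity collapse (default 0.2).
#' @param exploration_fraction fraction of the budget spent in the
#'   exploration phase (default 0.25).
#' @param chaotic_draws if `TRUE` (the multi-chaotic variant) the scalar
#'   steering draws (exploration jump, leader assessment, follower step
#'   fraction) come from the chaotic map; if `FALSE` they are uniform
#'   pseudo-random, as in the original algorithm. Normal deviates (Levy
#'   components, role perturbations) are pseudo-random in both variants.
#' @param reinit enable diversity-triggered reinitialization (default TRUE;
#'   the original algorithm has none).
#' @param c1,c2,a_start,a_end legacy coefficients retained in the
#'   configuration for completeness; they enter no update rule.
#' @return a list of class `heoa_config`.
#' @export
heoa_config <- function(pop_size = 30, max_iters = 500, map = "tent",
                        seed = 1, assessment = 0.6, jump_divisor = 1000,
                        levy_gamma = 1.5, diversity_threshold = 0.01,
                        reinit_fraction = 0.2, exploration_fraction = 0.25,
                        chaotic_draws = TRUE, reinit = TRUE,
                        c1 = 0.4, c2 = 0.3, a_start = 2, a_end = 0) {
  map <- match.arg(map, CHAOS_MAPS)
  stopifnot(pop_size >= 5, max_iters >= 4,
            reinit_fraction > 0, reinit_fraction < 1,
            jump_divisor >= 100, jump_divisor <= 2000)
  structure(
    list(pop_size = as.integer(pop_size), max_iters = as.integer(max_iters),
         map = map, seed = as.integer(seed), assessment = assessment,
         jump_divisor = jump_divisor, levy_gamma = levy_gamma,
         diversity_threshold = diversity_threshold,
         reinit_fraction = reinit_fraction,
         exploration_fraction = exploration_fraction,
         chaotic_draws = chaotic_draws, reinit = reinit,
         c1 = c1, c2 = c2, a_start = a_start, a_end = a_end),
    class = "heoa_config"
  )
}

#' Mantegna Levy-flight step vector
#'
#' Per component \eqn{\mu \sigma / |v|^{1/\gamma}} with \eqn{\mu, v}
#' standard normal and \eqn{\sigma} from the closed form
#' \eqn{\sigma = [\Gamma(1+\gamma)\sin(\pi\gamma/2) /
#' (\Gamma((1+\gamma)/2)\,\gamma\,2^{(\gamma-1)/2})]^{1/\gamma}}
#' (about 0.6966 at \eqn{\gamma = 1.5}).
#'
#' @param n number of components.
#' @param gamma stability index (default 1.5).
#' @param seed integer seed.
#' @return a numeric vector of `n` heavy-tailed steps.
#' @export
levy_flight <- function(n, gamma = 1.5, seed = 1) {
  stream <- new_rng_stream(seed, "levy")
  levy_draw(n, gamma, stream)
}

levy_sigma <- function(gamma = 1.5) {
  (gamma(1 + gamma) * sin(pi * gamma / 2) /
     (gamma((1 + gamma) / 2) * gamma * 2^((gamma - 1) / 2)))^(1 / gamma)
}

levy_draw <- function(n, gamma, stream) {
  mu <- stream_rnorm(stream, n)
  v <- stream_rnorm(stream, n)
  mu * levy_sigma(gamma) / abs(v)^(1 / gamma)
}

#' Knowledge-acquisition ease coefficient
#'
#' The development-phase step-size schedule
#' \eqn{\omega = 0.2\cos(\frac{\pi}{2}(1 - t/T))}: 0 at the start of the
#' run, 0.2 at the end.
#'
#' @param t current iteration (0-based, `0 <= t <= T`).
#' @param T iteration budget.
#' @return a scalar in `[0, 0.2]`.
#' @export
omega_coef <- function(t, T) {
  stopifnot(t >= 0, t <= T)
  0.2 * cos(pi / 2 * (1 - t / T))
}

#' Assign development-phase roles by fitness rank
#'
#' Stable ascending sort (minimization); the top 40% of ranks are leaders,
#' 40-80% explorers, 80-90% followers and the rest losers, with cutoffs
#' `ceiling(0.4 N)`, `ceiling(0.8 N)`, `ceiling(0.9 N)`. Ties keep insertion
#' order.
#'
#' @param fitness numeric vector of evaluated fitnesses.
#' @return a character vector of roles aligned with `fitness`.
#' @export
assign_roles <- function(fitness) {
  n <- length(fitness)
  ord <- order(fitness)                 # radix sort: stable on ties
  cut1 <- ceiling(0.4 * n)
  cut2 <- ceiling(0.8 * n)
  cut3 <- ceiling(0.9 * n)
  roles <- character(n)
  roles[ord[seq_len(cut1)]] <- "leader"
  roles[ord[seq(cut1 + 1, cut2)]] <- "explorer"
  roles[ord[seq(cut2 + 1, cut3)]] <- "follower"
  if (cut3 < n) roles[ord[seq(cut3 + 1, n)]] <- "loser"
  roles
}

#' Normalized population diversity
#'
#' Mean over dimensions of the per-dimension population standard deviation
#' (n denominator) of positions, normalized by the box width.
#'
#' @param positions N x D matrix of positions.
#' @param lower,upper scalar box bounds.
#' @return a scalar; 0 when all individuals coincide.
#' @export
population_diversity <- function(positions, lower, upper) {
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  mean(apply(positions, 2, pop_sd)) / (upper - lower)
}

clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# Replace the worst ceiling(fraction * N) rows with fresh chaotic positions.
reinit_bottom <- function(positions, fitness, fraction, lower, upper, chaos) {
  n <- nrow(positions)
  k <- ceiling(fraction * n)
  worst <- order(fitness, decreasing = TRUE)[seq_len(k)]
  fresh <- matrix(chaos$draw(k * ncol(positions)), nrow = k, byrow = TRUE)
  positions[worst, ] <- lower + (upper - lower) * fresh
  list(positions = positions, replaced = worst)
}

#' Run the optimizer
#'
#' Minimizes `objective` over the box `[lower, upper]^dim`. An
#' [objective()] spec supplies its own function, bounds and dimension; a
#' bare function requires them explicitly. A separately tracked global best
#' is never lost (elitist bookkeeping only; position updates themselves are
#' accepted unconditionally). Fully deterministic given the configuration
#' seed.
#'
#' @param objective an `objective_spec` or a function mapping a `dim`-vector
#'   to a scalar.
#' @param config an [heoa_config()].
#' @param dim,lower,upper problem geometry; taken from the spec when
#'   `objective` is one. `lower`/`upper` are scalars applied to every
#'   coordinate.
#' @param on_iteration optional callback `function(t, positions, fitness)`
#'   invoked after each iteration's evaluations (used e.g. to log
#'   per-generation diagnostics).
#' @return an object of class `heoa_result`: `best_position`,
#'   `best_fitness`, `initial_best`, `evals`, `trace` (a tibble with one row
#'   per iteration: `iteration`, `phase`, `best`, `diversity`, `reinit`),
#'   and the `config`.
#' @examples
#' res <- heoa_optimize(objective("sphere", dim = 5),
#'                      heoa_config(pop_size = 10, max_iters = 50, seed = 7))
#' res$best_fitness <= res$initial_best
#' @export
heoa_optimize <- function(objective, config = heoa_config(), dim = NULL,
                          lower = NULL, upper = NULL, on_iteration = NULL) {
  if (inherits(objective, "objective_spec")) {
    dim <- objective$dim
    lower <- objective$lower
    upper <- objective$upper
    obj_fun <- function(x) evaluate_objective(objective, x)
  } else {
    stopifnot(is.function(objective), !is.null(dim), !is.null(lower),
              !is.null(upper))
    obj_fun <- objective
  }
  N <- config$pop_size
  T <- config$max_iters
  D <- as.integer(dim)
  seed <- config$seed

  evals <- 0L
  eval_row <- function(x) {
    evals <<- evals + 1L
    val <- obj_fun(x)
    if (!is.finite(val)) val <- .Machine$double.xmax
    val
  }

  init_chaos <- chaos_stream(config$map, derive_seed(seed, "init"))
  move_chaos <- chaos_stream(config$map, derive_seed(seed, "moves"))
  reinit_chaos <- chaos_stream(config$map, derive_seed(seed, "reinit"))
  gauss <- new_rng_stream(seed, "gauss")
  unif <- new_rng_stream(seed, "unif")

  # chaotic initialization: N x D unit values mapped affinely into the box
  positions <- lower + (upper - lower) *
    matrix(init_chaos$draw(N * D), nrow = N, byrow = TRUE)
  fitness <- apply(positions, 1, eval_row)

  best_idx <- which.min(fitness)
  best_pos <- positions[best_idx, ]
  best_fit <- fitness[best_idx]
  initial_best <- best_fit

  f_jump <- (lower - upper) / config$jump_divisor
  explore_until <- T * config$exploration_fraction

  best_hist <- numeric(T)
  div_hist <- numeric(T)
  phase_hist <- character(T)
  reinit_hist <- logical(T)

  scalar_draw <- function(n) {
    if (config$chaotic_draws) move_chaos$draw(n) else stream_runif(unif, n)
  }

  for (t in 0:(T - 1)) {
    exploring <- t < explore_until
    om <- omega_coef(t, T)
    if (exploring) {
      x_mean <- colMeans(positions)
      decay <- 1 - t / T
      levy <- matrix(levy_draw(N * D, config$levy_gamma, gauss), nrow = N)
      r <- scalar_draw(N)
      jump <- floor(r / f_jump) * f_jump
      beta <- 0.2 * decay * sweep(positions, 2, x_mean)
      newpos <- beta * decay * sweep(positions, 2, best_pos) * levy +
        matrix(best_pos * decay, N, D, byrow = TRUE) +
        outer(jump, x_mean - best_pos)
    } else {
      roles <- assign_roles(fitness)
      worst_pos <- positions[which.max(fitness), ]
      newpos <- positions
      for (i in seq_len(N)) {
        xi <- positions[i, ]
        newpos[i, ] <- switch(roles[i],
          leader = {
            R <- scalar_draw(1)
            if (R < config$assessment) {
              r <- max(stream_runif(unif, 1), .Machine$double.eps)
              om * xi * exp(-t / (r * T))
            } else {
              om * xi + stream_rnorm(gauss, 1)
            }
          },
          explorer = {
            # squared-difference-over-2 reading of the exponent, clamped to
            # +/-50: the raw form overflows on wide domains. An alternate
            # reading uses ||X_worst||^2 - ||X_i||^2 (scalar); rejected as
            # it loses the per-coordinate contrast.
            rn <- stream_rnorm(gauss, D)
            rn * exp(pmin(pmax((worst_pos^2 - xi^2) / 2, -50), 50))
          },
          follower = {
            rd <- 1 + scalar_draw(1) * (D - 1)
            xi + om * rd * (best_pos - xi)
          },
          loser = {
            best_pos + (best_pos - xi) * stream_rnorm(gauss, 1)
          }
        )
      }
    }
    positions <- clip_box(newpos, lower, upper)
    fitness <- apply(positions, 1, eval_row)

    reinit_now <- FALSE
    div <- population_diversity(positions, lower, upper)
    if (config$reinit && !exploring && div < config$diversity_threshold) {
      rb <- reinit_bottom(positions, fitness, config$reinit_fraction,
                          lower, upper, reinit_chaos)
      positions <- rb$positions
      fitness[rb$replaced] <- apply(positions[rb$replaced, , drop = FALSE],
                                    1, eval_row)
      div <- population_diversity(positions, lower, upper)
      reinit_now <- TRUE
    }

    it_best <- which.min(fitness)
    if (fitness[it_best] < best_fit) {
      best_fit <- fitness[it_best]
      best_pos <- positions[it_best, ]
    }

    best_hist[t + 1] <- best_fit
    div_hist[t + 1] <- div
    phase_hist[t + 1] <- if (exploring) "exploration" else "development"
    reinit_hist[t + 1] <- reinit_now
    if (!is.null(on_iteration)) on_iteration(t + 1, positions, fitness)
  }

  structure(
    list(best_position = best_pos, best_fitness = best_fit,
         initial_best = initial_best, evals = evals,
         trace = tibble::tibble(iteration = seq_len(T), phase = phase_hist,
                                best = best_hist, diversity = div_hist,
                                reinit = reinit_hist),
         config = config),
    class = "heoa_result"
  )
}

#' @export
print.heoa_result <- function(x, ...) {
  cat(sprintf("<heoa_result> map=%s N=%d T=%d seed=%d\n",
              x$config$map, x$config$pop_size, x$config$max_iters,
              x$config$seed))
  cat(sprintf("  best fitness: %.6g (initial %.6g), %d evaluations\n",
              x$best_fitness, x$initial_best, x$evals))
  invisible(x)
}
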