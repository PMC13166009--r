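# Benchmark objective functions and run statistics.
#
# Ten box-constrained minimization problems: five classics (Sphere,
# Rosenbrock, Rastrigin, Ackley, Griewank) and their shifted variants, each
# with known optimum value 0. Shifts displace the optimum to a seeded point
# in the middle half of the domain so that symmetry about the origin cannot
# be exploited.

BENCH_BASE <- tibble::tibble(
  name  = c("sphere", "rosenbrock", "rastrigin", "ackley", "griewank"),
  lower = c(-100, -100, -5.12, -32, -600),
  upper = c(100, 100, 5.12, 32, 600)
)

bench_fn <- function(name) {
  switch(name,
    sphere = function(x) sum(x^2),
    rosenbrock = function(x) {
      d <- length(x)
      sum(100 * (x[-1] - x[-d]^2)^2 + (1 - x[-d])^2)
    },
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    ackley = function(x) {
      d <- length(x)
      -20 * exp(-0.2 * sqrt(sum(x^2) / d)) - exp(sum(cos(2 * pi * x)) / d) +
        20 + exp(1)
    },
    griewank = function(x) {
      1 + sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x))))
    },
    stop(sprintf("unknown benchmark function '%s'", name), call. = FALSE)
  )
}

#' Benchmark objective specification
#'
#' Builds one of the five classic objectives at a given dimension. All have
#' a global minimum value of 0 (at the origin, or at `(1, ..., 1)` for
#' Rosenbrock); evaluation is defined everywhere, bounds describe the search
#' box.
#'
#' @param name one of `"sphere"`, `"rosenbrock"`, `"rastrigin"`,
#'   `"ackley"`, `"griewank"`.
#' @param dim problem dimensionality (default 30).
#' @return an object of class `objective_spec` with fields `name`, `dim`,
#'   `lower`, `upper`, `shift` (NULL here) and `fn`.
#' @examples
#' obj <- objective("rastrigin", dim = 2)
#' evaluate_objective(obj, c(0.5, 0)) # 20.25
#' @export
objective <- function(name, dim = 30) {
  name <- match.arg(name, BENCH_BASE$name)
  row <- BENCH_BASE[BENCH_BASE$name == name, ]
  structure(
    list(name = name, dim = as.integer(dim), lower = row$lower,
         upper = row$upper, shift = NULL, fn = bench_fn(name)),
    class = "objective_spec"
  )
}

#' Evaluate an objective at a point
#'
#' Shifted objectives evaluate the base function at `x - shift`, so the
#' translation identity `f_shift(x) = f_base(x - shift)` holds exactly.
#'
#' @param obj an [objective()] spec.
#' @param x numeric vector of length `obj$dim`.
#' @return the objective value (a scalar).
#' @export
evaluate_objective <- function(obj, x) {
  stopifnot(inherits(obj, "objective_spec"))
  if (length(x) != obj$dim) {
    stop(sprintf("expected a vector of length %d, got %d", obj$dim, length(x)),
         call. = FALSE)
  }
  if (!is.null(obj$shift)) x <- x - obj$shift
  obj$fn(x)
}

#' Shift an objective to a seeded optimum location
#'
#' Draws a shift vector component-wise uniformly from the middle half of the
#' domain (so the displaced optimum stays well inside the bounds) and
#' returns a new spec whose optimum sits at the shift. Deterministic given
#' the seed.
#'
#' @param base an unshifted [objective()] spec.
#' @param seed integer seed for the shift draw.
#' @return an `objective_spec` with a non-NULL `shift`.
#' @export
make_shifted <- function(base, seed) {
  stopifnot(inherits(base, "objective_spec"))
  if (!is.null(base$shift)) stop("objective is already shifted", call. = FALSE)
  mid <- (base$lower + base$upper) / 2
  half <- (base$upper - base$lower) / 4
  shift <- stream_runif(new_rng_stream(seed, paste0("shift-", base$name)),
                        base$dim, mid - half, mid + half)
  out <- base
  out$name <- paste0("shifted_", base$name)
  out$shift <- shift
  out
}

#' The ten-function benchmark suite
#'
#' The five classics plus their seeded shifted variants, in the fixed order
#' used throughout the harness.
#'
#' @param dim dimensionality (default 30).
#' @param seed integer seed controlling the shift vectors.
#' @return a named list of ten `objective_spec` objects.
#' @export
benchmark_suite <- function(dim = 30, seed = 1) {
  base <- lapply(BENCH_BASE$name, objective, dim = dim)
  shifted <- lapply(seq_along(base), function(i) {
    make_shifted(base[[i]], derive_seed(seed, paste0("suite-", i)))
  })
  out <- c(base, shifted)
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Fraction of runs reaching the optimum within tolerance
#'
#' All suite optima are 0, so a run succeeds when its final best value is at
#' or below the tolerance.
#'
#' @param finals numeric vector of final best values, one per run.
#' @param tolerance success threshold (default 1e-3).
#' @return fraction in `[0, 1]`.
#' @export
success_rate <- function(finals, tolerance = 1e-3) {
  if (length(finals) == 0) stop("at least one run is required", call. = FALSE)
  mean(finals <= tolerance)
}

#' Iterations needed to reach a precision
#'
#' 1-based index of the first best-so-far value at or below the tolerance;
#' `length(history) + 1` when the tolerance is never reached (a sentinel one
#' past the end).
#'
#' @param history numeric vector of best-so-far values per iteration.
#' @param tolerance precision threshold (default 1e-3).
#' @return an integer in `1..(length(history) + 1)`.
#' @export
convergence_speed <- function(history, tolerance = 1e-3) {
  if (length(history) == 0) stop("history must be non-empty", call. = FALSE)
  hit <- which(history <= tolerance)
  if (length(hit) == 0) length(history) + 1L else hit[1]
}

#' Summarize harness run records
#'
#' Aggregates per-run final best values and convergence histories into one
#' row per (map, function) cell: mean, sample standard deviation (n - 1
#' denominator), median, best, worst, success rate at the tolerance, and
#' mean convergence speed in iterations.
#'
#' @param records a tibble as returned by [run_harness()], with columns
#'   `map`, `fn`, `run`, `final_best` and list-column `history`.
#' @param tolerance success threshold (default 1e-3).
#' @return a tibble with one row per (map, fn).
#' @export
summarize_runs <- function(records, tolerance = 1e-3) {
  stopifnot(nrow(records) >= 1)
  records |>
    dplyr::group_by(.data$map, .data$fn) |>
    dplyr::summarise(
      runs = dplyr::n(),
      mean = mean(.data$final_best),
      std = stats::sd(.data$final_best),
      median = stats::median(.data$final_best),
      best = min(.data$final_best),
      worst = max(.data$final_best),
      success_rate = success_rate(.data$final_best, tolerance),
      mean_convergence_speed = mean(vapply(.data$history, convergence_speed,
                                           numeric(1), tolerance = tolerance)),
      .groups = "drop"
    )
}

#' Win table across chaotic maps
#'
#' Attributes each benchmark function to the map with the lowest mean final
#' best value; ties go to the earlier map in the fixed order (logistic,
#' tent, sine, henon, chebyshev, circle). Wins always sum to the number of
#' functions.
#'
#' @param summary a tibble from [summarize_runs()].
#' @return a tibble with columns `map`, `wins`, `rate`, sorted by wins.
#' @export
win_table <- function(summary) {
  map_order <- CHAOS_MAPS
  winners <- summary |>
    dplyr::mutate(map_rank = match(.data$map, map_order)) |>
    dplyr::group_by(.data$fn) |>
    dplyr::arrange(.data$mean, .data$map_rank, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  n_fn <- dplyr::n_distinct(summary$fn)
  tibble::tibble(map = intersect(map_order, unique(summary$map))) |>
    dplyr::left_join(dplyr::count(winners, .data$map, name = "wins"), by = "map") |>
    dplyr::mutate(wins = dplyr::coalesce(.data$wins, 0L),
                  rate = .data$wins / n_fn) |>
    dplyr::arrange(dplyr::desc(.data$wins), match(.data$map, map_order))
}
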