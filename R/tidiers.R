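# broom-style tidiers for fitted/searched objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an optimizer run
#'
#' @param x an `heoa_result`.
#' @param ... unused.
#' @return the per-iteration trace tibble (`iteration`, `phase`, `best`,
#'   `diversity`, `reinit`).
#' @export
tidy.heoa_result <- function(x, ...) {
  x$trace
}

#' One-row summary of an optimizer run
#'
#' @param x an `heoa_result`.
#' @param ... unused.
#' @return a one-row tibble: map, population, iterations, seed, initial and
#'   final best, improvement factor, evaluation count, reinit events.
#' @export
glance.heoa_result <- function(x, ...) {
  tibble::tibble(
    map = x$config$map,
    pop_size = x$config$pop_size,
    max_iters = x$config$max_iters,
    seed = x$config$seed,
    initial_best = x$initial_best,
    best_fitness = x$best_fitness,
    improvement = x$initial_best / max(x$best_fitness, .Machine$double.xmin),
    evals = x$evals,
    reinit_events = sum(x$trace$reinit)
  )
}

#' Tidy an architecture search
#'
#' @param x an `nas_result`.
#' @param ... unused.
#' @return the per-generation history tibble (`generation`,
#'   `valid_fraction`, `evaluator_calls`, `best_fitness`).
#' @export
tidy.nas_result <- function(x, ...) {
  x$history
}

#' One-row summary of an architecture search
#'
#' @param x an `nas_result`.
#' @param ... unused.
#' @return a one-row tibble: best fitness, accuracy, parameter count,
#'   budget flag, layer count, evaluator label and call count.
#' @export
glance.nas_result <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    accuracy = x$accuracy,
    total_params = x$report$total,
    fpga_ok = x$report$fpga_ok,
    n_layers = nrow(x$best_arch$layers),
    evaluator = x$evaluator_label,
    evaluator_calls = x$evaluator_calls
  )
}

#' Tidy a harness result
#'
#' @param x a `harness_result`.
#' @param ... unused.
#' @return the per-cell summary tibble.
#' @export
tidy.harness_result <- function(x, ...) {
  x$summary
}

#' One-row-per-map summary of a harness run
#'
#' @param x a `harness_result`.
#' @param ... unused.
#' @return the win table.
#' @export
glance.harness_result <- function(x, ...) {
  x$wins
}
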