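# Benchmark harness: maps x functions x runs grid with tidy outputs.

#' Run the chaotic-map benchmark grid
#'
#' Executes the optimizer for every combination of chaotic map, benchmark
#' function and run index, with per-combination seeds derived from the
#' master seed. Returns tidy records plus the per-cell statistical summary
#' and the win table. Deterministic given the configuration.
#'
#' @param maps character vector of chaotic maps (default all six).
#' @param functions character vector of suite function names (default all
#'   ten; see [benchmark_suite()]).
#' @param runs independent runs per cell (default 30).
#' @param pop_size,max_iters optimizer budget per run (defaults 30 and 500).
#' @param dim problem dimensionality (default 30).
#' @param seed master seed; controls shifts and every run.
#' @param tolerance success threshold for the summary statistics.
#' @param out_dir optional directory; when given, per-run histories
#'   (`records.csv`), the summary (`summary.csv`), the win table
#'   (`wins.csv`) and the full configuration (`config.json`) are written
#'   there.
#' @return a list of class `harness_result`: `records` (tibble: `map`,
#'   `fn`, `run`, `final_best`, list-column `history`), `summary`, `wins`,
#'   `config`.
#' @export
run_harness <- function(maps = CHAOS_MAPS, functions = NULL, runs = 30,
                        pop_size = 30, max_iters = 500, dim = 30, seed = 7,
                        tolerance = 1e-3, out_dir = NULL) {
  suite <- benchmark_suite(dim = dim, seed = seed)
  if (is.null(functions)) functions <- names(suite)
  missing_fn <- setdiff(functions, names(suite))
  if (length(missing_fn) > 0) {
    stop(sprintf("unknown benchmark function(s): %s",
                 paste(missing_fn, collapse = ", ")), call. = FALSE)
  }
  maps <- vapply(maps, match.arg, character(1), choices = CHAOS_MAPS)

  grid <- tidyr::expand_grid(map = maps, fn = functions, run = seq_len(runs))
  records <- purrr::pmap(grid, function(map, fn, run) {
    cfg <- heoa_config(pop_size = pop_size, max_iters = max_iters, map = map,
                       seed = derive_seed(seed, paste(map, fn, run, sep = "/")))
    res <- heoa_optimize(suite[[fn]], cfg)
    tibble::tibble(map = map, fn = fn, run = run,
                   final_best = res$best_fitness,
                   history = list(res$trace$best))
  }) |> dplyr::bind_rows()

  summary <- summarize_runs(records, tolerance = tolerance)
  wins <- win_table(summary)
  config <- list(maps = maps, functions = functions, runs = runs,
                 pop_size = pop_size, max_iters = max_iters, dim = dim,
                 seed = seed, tolerance = tolerance)
  out <- structure(list(records = records, summary = summary, wins = wins,
                        config = config),
                   class = "harness_result")
  if (!is.null(out_dir)) write_harness(out, out_dir)
  out
}

write_harness <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  long <- result$records |>
    dplyr::mutate(iteration = purrr::map(.data$history, seq_along)) |>
    tidyr::unnest(c("history", "iteration")) |>
    dplyr::rename(best = "history") |>
    dplyr::select("map", "fn", "run", "iteration", "best")
  utils::write.csv(long, file.path(out_dir, "records.csv"), row.names = FALSE)
  utils::write.csv(result$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$wins, file.path(out_dir, "wins.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.harness_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<harness_result> %d maps x %d functions x %d runs (N=%d, T=%d, D=%d)\n",
              length(cfg$maps), length(cfg$functions), cfg$runs,
              cfg$pop_size, cfg$max_iters, cfg$dim))
  print(x$wins)
  invisible(x)
}

#' Search-budget arithmetic
#'
#' Accounting identities for a selectively trained search: the effective
#' number of training runs is `pop * gens * valid_ratio` (infeasible
#' candidates are rejected before training), total epochs multiply by the
#' mean epochs per trained candidate, and total mini-batch passes multiply
#' again by the batches per epoch.
#'
#' @param pop population size.
#' @param gens number of generations.
#' @param valid_ratio fraction of candidates that pass the feasibility
#'   gate.
#' @param epochs_per_candidate mean training epochs per feasible candidate.
#' @param batches_per_epoch mini-batches per epoch (see
#'   [batches_per_epoch()]).
#' @return a one-row tibble: `effective_runs`, `total_epochs`,
#'   `total_batches`.
#' @examples
#' budget_report(20, 100, 0.6, 11, 66)
#' @export
budget_report <- function(pop, gens, valid_ratio, epochs_per_candidate,
                          batches_per_epoch) {
  stopifnot(pop > 0, gens > 0, valid_ratio > 0, epochs_per_candidate > 0,
            batches_per_epoch > 0)
  effective_runs <- pop * gens * valid_ratio
  total_epochs <- effective_runs * epochs_per_candidate
  tibble::tibble(effective_runs = effective_runs,
                 total_epochs = total_epochs,
                 total_batches = total_epochs * batches_per_epoch)
}

#' Mini-batches per training epoch
#'
#' @param n_train number of training items.
#' @param batch_size mini-batch size.
#' @return `ceiling(n_train / batch_size)`.
#' @examples
#' batches_per_epoch(2100, 32) # 66
#' @export
batches_per_epoch <- function(n_train, batch_size) {
  stopifnot(n_train > 0, batch_size > 0)
  as.integer(ceiling(n_train / batch_size))
}
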