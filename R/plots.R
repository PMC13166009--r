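# ggplot2 views of traces and harness results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Convergence trace of one optimizer run
#'
#' Best-so-far fitness per iteration on a log10 scale, with the phase
#' switch and any diversity-triggered reinitializations marked.
#'
#' @param object an `heoa_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.heoa_result <- function(object, ...) {
  tr <- object$trace
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$best)) +
    ggplot2::geom_line(ggplot2::aes(color = .data$phase, group = 1)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "best-so-far fitness",
                  color = "phase",
                  title = sprintf("%s map, N = %d", object$config$map,
                                  object$config$pop_size)) +
    ggplot2::theme_minimal()
  ev <- tr[tr$reinit, ]
  if (nrow(ev) > 0) {
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$iteration),
                                 linetype = "dotted", alpha = 0.5)
  }
  p
}

#' Final-best distributions across maps and functions
#'
#' One boxplot per chaotic map, faceted by benchmark function, of the
#' final best values across runs (log10 scale).
#'
#' @param object a `harness_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.harness_result <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$map, y = .data$final_best)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~fn, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "final best fitness") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Search progress of an architecture search
#'
#' Best fitness and feasible fraction per generation.
#'
#' @param object an `nas_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nas_result <- function(object, ...) {
  long <- object$history |>
    tidyr::pivot_longer(c("best_fitness", "valid_fraction"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}

#' Gallery of synthetic images
#'
#' Raster montage of one image per class (or `n_each` per class).
#'
#' @param object a `synthetic_image_set`.
#' @param n_each images per class to show (default 1).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.synthetic_image_set <- function(object, n_each = 1, ...) {
  picks <- unlist(lapply(levels(object$labels), function(cl) {
    utils::head(which(object$labels == cl), n_each)
  }))
  df <- dplyr::bind_rows(lapply(picks, function(i) {
    img <- object$images[i, , ]
    tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img))) |>
      dplyr::mutate(value = as.vector(t(img)),
                    label = as.character(object$labels[i]), id = i)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::facet_wrap(~label + id) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
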