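# Genome codec for compact convolutional classifiers.
#
# A candidate architecture is a point in the unit hypercube [0,1]^28,
# decoded deterministically into: a depth L in 2..10 (gene 1), per-layer
# kinds (genes 2-10: standard conv / depthwise separable / skip), per-layer
# output channels on the 16-multiples lattice [32, 512] (genes 11-19),
# three typed pooling slots (genes 20-22) with positions (genes 23-25; gene
# 26 is reserved), a fully connected width (gene 27) and a dropout rate
# (gene 28). Decoding is total: every genome yields an architecture;
# structural problems are reported by the validator, not by the decoder.

LAYER_KINDS <- c("standard_conv", "depthwise_separable", "skip")
POOL_KINDS <- c("none", "max", "avg")
FC_DIMS <- c(64L, 128L, 256L, 512L)
PARAM_BUDGET <- 1e6

#' Decode a genome into an architecture
#'
#' @param genome numeric vector of exactly 28 values in `[0, 1]`.
#' @return a list of class `architecture_spec`: `input` (224 x 224 x 1),
#'   `layers` (tibble with `kind`, `out_channels`, `pooling_after`),
#'   `fc_dim`, `dropout`, `classes` (4).
#' @examples
#' arch <- decode_genome(rep(0.5, 28))
#' arch$layers
#' @export
decode_genome <- function(genome) {
  if (length(genome) != 28) {
    stop(sprintf("genome must have exactly 28 values, got %d", length(genome)),
         call. = FALSE)
  }
  if (any(genome < 0 | genome > 1)) {
    stop("all genome values must lie in [0, 1]", call. = FALSE)
  }
  L <- min(floor(2 + 9 * genome[1]), 10)
  kind_gene <- genome[2:(1 + L)]
  kinds <- ifelse(kind_gene < 0.33, "standard_conv",
                  ifelse(kind_gene < 0.67, "depthwise_separable", "skip"))
  ch_gene <- genome[11:(10 + L)]
  channels <- pmin(pmax(16 * round((32 + ch_gene * 480) / 16), 32), 512)

  pool_type <- POOL_KINDS[pmin(floor(genome[20:22] * 3) + 1, 3)]
  pool_pos <- pmin(pmax(floor(genome[23:25] * L) + 1, 1), L)
  pooling_after <- rep("none", L)
  for (s in 3:1) {                      # earlier slot wins on a collision
    if (pool_type[s] != "none") pooling_after[pool_pos[s]] <- pool_type[s]
  }

  fc_dim <- FC_DIMS[pmin(floor(genome[27] * 4) + 1, 4)]
  structure(
    list(
      input = c(224L, 224L, 1L),
      layers = tibble::tibble(kind = kinds,
                              out_channels = as.integer(channels),
                              pooling_after = pooling_after),
      fc_dim = fc_dim,
      dropout = 0.8 * genome[28],
      classes = 4L,
      pool_slots = tibble::tibble(type = pool_type, position = pool_pos)
    ),
    class = "architecture_spec"
  )
}

#' Structural validation of a decoded architecture
#'
#' Returns a character vector of violations; an empty vector means the
#' architecture is structurally sound. Checked: spatial collapse (the input
#' side is halved by each pooling; the final size must stay at least 1), a
#' skip connection in the first position (there is no channel stream to
#' pass through), and pooling slots colliding on one layer (coalesced to a
#' single pooling by the decoder, reported here).
#'
#' @param arch an [decode_genome()] result.
#' @return character vector of violation messages (possibly empty).
#' @export
validate_architecture <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  violations <- character(0)
  n_pool <- sum(arch$layers$pooling_after != "none")
  final_size <- arch$input[1] %/% 2^n_pool
  if (final_size < 1) {
    violations <- c(violations, sprintf(
      "spatial collapse: %d poolings reduce %d to below 1", n_pool,
      arch$input[1]))
  }
  if (arch$layers$kind[1] == "skip") {
    violations <- c(violations, "skip connection in first position")
  }
  active <- arch$pool_slots[arch$pool_slots$type != "none", ]
  if (anyDuplicated(active$position)) {
    violations <- c(violations, "duplicate pooling positions (coalesced to one)")
  }
  violations
}

#' Count trainable parameters of an architecture
#'
#' Conventions: 3x3 kernels throughout, biases included, no normalization
#' layers. A standard convolution contributes
#' \eqn{9 C_{in} C_{out} + C_{out}}; a depthwise separable convolution
#' \eqn{9 C_{in} + C_{in} + C_{in} C_{out} + C_{out}} (3x3 depthwise with
#' bias, then 1x1 pointwise with bias); a skip layer is an identity
#' pass-through with zero parameters whose output channels equal its input
#' channels. Pooling is parameter-free. The classifier applies global
#' average pooling, then `C_last -> fc` and `fc -> 4` dense layers with
#' biases.
#'
#' @param arch an `architecture_spec`.
#' @return a list of class `param_report`: `per_layer` (tibble), `total`,
#'   `fpga_ok` (`total < 1e6`).
#' @examples
#' g <- rep(0.5, 28)
#' count_params(decode_genome(g))$total
#' @export
count_params <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  c_in <- arch$input[3]
  rows <- vector("list", nrow(arch$layers) + 2)
  for (i in seq_len(nrow(arch$layers))) {
    kind <- arch$layers$kind[i]
    c_out <- arch$layers$out_channels[i]
    p <- switch(kind,
      standard_conv = 9 * c_in * c_out + c_out,
      depthwise_separable = 9 * c_in + c_in + c_in * c_out + c_out,
      skip = { c_out <- c_in; 0 }
    )
    rows[[i]] <- tibble::tibble(layer = sprintf("layer_%d (%s)", i, kind),
                                params = p)
    c_in <- c_out
  }
  n <- nrow(arch$layers)
  rows[[n + 1]] <- tibble::tibble(
    layer = sprintf("fc (%d -> %d)", c_in, arch$fc_dim),
    params = c_in * arch$fc_dim + arch$fc_dim)
  rows[[n + 2]] <- tibble::tibble(
    layer = sprintf("classifier (%d -> %d)", arch$fc_dim, arch$classes),
    params = arch$fc_dim * arch$classes + arch$classes)
  per_layer <- dplyr::bind_rows(rows)
  total <- sum(per_layer$params)
  structure(list(per_layer = per_layer, total = total,
                 fpga_ok = total < PARAM_BUDGET),
            class = "param_report")
}

#' Budget-gated multi-objective fitness
#'
#' Scalarizes validation accuracy against parameter compactness:
#' \eqn{w_{acc}\,acc - w_{params}\,params/10^6} for architectures under the
#' one-million-parameter budget, and a flat penalty of -1000 at or above
#' it, which makes any over-budget candidate strictly dominated by every
#' feasible one.
#'
#' @param val_accuracy validation accuracy in `[0, 1]`.
#' @param total_params total trainable parameter count.
#' @param w_acc,w_params scalarization weights (defaults 0.7 and 0.3).
#' @return a scalar fitness (to be maximized).
#' @examples
#' nas_fitness(0.5294, 724200) # 0.15332
#' @export
nas_fitness <- function(val_accuracy, total_params, w_acc = 0.7,
                        w_params = 0.3) {
  if (val_accuracy < 0 || val_accuracy > 1) {
    stop("val_accuracy must lie in [0, 1]", call. = FALSE)
  }
  if (total_params >= PARAM_BUDGET) return(-1000)
  w_acc * val_accuracy - w_params * total_params / PARAM_BUDGET
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %d layers, fc %d, dropout %.2f, input %s\n",
              nrow(x$layers), x$fc_dim, x$dropout,
              paste(x$input, collapse = "x")))
  print(x$layers)
  invisible(x)
}

#' @export
print.param_report <- function(x, ...) {
  print(x$per_layer)
  cat(sprintf("total %d parameters; under budget: %s\n", x$total,
              x$fpga_ok))
  invisible(x)
}
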