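# Model construction and parameter accounting.
#
# Block layout (levels are indexed 1..L, shallow to deep; ch[d] is the
# level width):
#   * Encoder: one 3x3 conv unit (conv + BN + ReLU) per step at every
#     level. The level-1 conv consumes [image, backward], levels 2..L-1
#     consume the 2x2-max-pooled concatenation [encoder output above,
#     backward feature above], and the bottom level L consumes the output
#     of its entry conv. Backward features are the previous pass's
#     decoder outputs (zero on the very first pass).
#   * Decoder: one 3x3 conv unit per step at levels 1..L-1, consuming the
#     forward-skip concatenation [same-level encoder output, learned 2x2
#     up-convolution of the level below], followed by one shared (step-
#     independent) 3x3 refinement conv unit per level.
#   * Stage bottoms: the deepest stage owns an entry conv (lifting
#     ch[L-1] to ch[L]) and a refinement conv at level L; the stage below
#     owns a refinement conv at its own bottom, level L-1.
#   * One 1x1 prediction head per stage producing the stage's
#     pre-activation map.
#
# Counting convention (fixed once): trainable scalars are the 3x3 and
# 1x1 conv kernels and biases, the 2x2 up-conv kernels and biases, and
# the batch-norm scale/shift pairs. Batch-norm running statistics are
# buffers, not parameters. One conv unit with `ci` inputs and `co`
# outputs therefore holds 9*ci*co + co + 2*co scalars.

kaiming <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

conv_unit_params <- function(ci, co) {
  list(W = kaiming(c(3, 3, ci, co), 9 * ci), b = numeric(co),
       g = rep(1, co), be = numeric(co))
}

#' Build a PL-Net model
#'
#' Allocates and initializes every trainable tensor for the architecture
#' described by `config`. Weights use Kaiming fan-in initialization and
#' depend on the R random seed in effect at the call.
#'
#' @param config a [plnet_config()].
#' @return An object of class `plnet_model`: the configuration, a named
#'   list of parameter arrays, and an environment of batch-norm running
#'   statistics.
#' @examples
#' set.seed(1)
#' m <- build_plnet(plnet_config(ocs = 0.25, input_size = 64))
#' count_parameters(m)
#' @export
build_plnet <- function(config) {
  stopifnot(inherits(config, "plnet_config"))
  ch <- config$channels; L <- length(ch)
  ns <- config$n_steps; K <- config$n_classes
  p <- list()
  add_unit <- function(p, name, ci, co) { p[[name]] <- conv_unit_params(ci, co); p }

  for (d in seq_len(L)) {
    ci <- if (d == 1L) config$in_channels + ch[1]
          else if (d < L) 2L * ch[d - 1L]
          else ch[L]                       # bottom step conv follows the entry conv
    if (config$n_stages == 1L && d == L) ci <- ch[L]
    for (s in seq_len(ns)) p <- add_unit(p, sprintf("enc%d_s%d", d, s), ci, ch[d])
  }
  for (d in seq_len(L - 1L)) {
    for (s in seq_len(ns)) p <- add_unit(p, sprintf("dec%d_s%d", d, s), 2L * ch[d], ch[d])
    p <- add_unit(p, sprintf("decr%d", d), ch[d], ch[d])
  }
  # deepest stage's bottom block
  p <- add_unit(p, "bott_entry", ch[L - 1L], ch[L])
  p <- add_unit(p, "bott_refine", ch[L], ch[L])
  if (config$n_stages == 2L) {
    # stage-1 bottom refinement at level L-1
    p <- add_unit(p, "s1_refine", ch[L - 1L], ch[L - 1L])
  }
  for (d in seq_len(L - 1L)) {
    p[[sprintf("up%d", d)]] <- list(
      W = kaiming(c(2, 2, ch[d + 1L], ch[d]), 4 * ch[d + 1L]),
      b = numeric(ch[d]))
  }
  for (n in seq_len(config$n_stages)) {
    p[[sprintf("head%d", n)]] <- list(
      W = matrix(stats::rnorm(ch[1] * K, 0, sqrt(2 / ch[1])), ch[1], K),
      b = numeric(K))
  }
  structure(list(config = config, params = p,
                 bn_stats = new.env(parent = emptyenv())),
            class = "plnet_model")
}

#' Count trainable parameters of a model
#'
#' Exact count of trainable scalars under the package's documented
#' convention: conv and up-conv kernels, biases, batch-norm scales and
#' shifts, and the prediction heads. Running statistics are excluded.
#'
#' @param model a `plnet_model`.
#' @return Integer scalar.
#' @examples
#' set.seed(1)
#' count_parameters(build_plnet(plnet_config(ocs = 0.25, input_size = 64)))
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "plnet_model"))
  sum(vapply(model$params, function(u) sum(vapply(u, length, integer(1))), numeric(1)))
}

#' @export
print.plnet_model <- function(x, ...) {
  cat(sprintf("PL-Net model: %d blocks, %s parameters (%.2f M)\n",
              length(x$params),
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  print(x$config)
  invisible(x)
}

# Parameter names exercised by a given stage's forward pass.
stage_param_names <- function(model, stage) {
  cfg <- model$config; L <- length(cfg$channels); ns <- cfg$n_steps
  last <- cfg$n_stages
  enc_top <- if (stage == last) L else L - 1L
  nm <- character()
  for (d in seq_len(min(enc_top, L - 1L)))
    nm <- c(nm, sprintf("enc%d_s%d", d, seq_len(ns)))
  if (stage == last) {
    nm <- c(nm, sprintf("enc%d_s%d", L, seq_len(ns)), "bott_entry", "bott_refine")
  } else {
    nm <- c(nm, "s1_refine")
  }
  dec_top <- if (stage == last) L - 1L else L - 2L
  for (d in seq_len(dec_top))
    nm <- c(nm, sprintf("dec%d_s%d", d, seq_len(ns)), sprintf("decr%d", d), sprintf("up%d", d))
  c(nm, sprintf("head%d", stage))
}
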