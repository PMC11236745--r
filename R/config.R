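# Architectural configuration.

#' Scale a channel plan by the output-channel scale (Ocs)
#'
#' Every level width is multiplied by `ocs` and rounded half-up, clamped
#' to at least one channel. `ocs = 0.5` on the default plan yields the
#' reduced PL-Net variant (roughly a quarter of the parameters, since the
#' dominant convolution terms are quadratic in width).
#'
#' @param base_channels integer vector of per-depth output channels.
#' @param ocs positive channel-scale factor.
#' @return Integer vector of scaled channel widths.
#' @examples
#' scale_channels(c(32, 64, 128, 256, 512), 0.5)
#' @export
scale_channels <- function(base_channels, ocs) {
  if (!is.numeric(ocs) || length(ocs) != 1L || !is.finite(ocs) || ocs <= 0)
    stop("`ocs` must be a single positive number")
  if (any(base_channels < 1)) stop("all base channels must be >= 1")
  as.integer(pmax(1, floor(base_channels * ocs + 0.5)))
}

#' Architectural hyperparameters for PL-Net
#'
#' Defines the channel plan, the number of internal "steps" (complete
#' encode-decode passes per stage, each with its own convolution per
#' block) and external "stages" (depth variants trained coarse-to-fine).
#' The deepest stage uses every level; the stage below it omits the
#' deepest level. With the defaults (224 px input, five levels 32-512,
#' two steps, two stages) the model has about 15.0 M trainable
#' parameters.
#'
#' For inputs smaller than 128 px the default five-level plan is
#' automatically reduced to four levels so that the bottom feature map
#' stays meaningful at small fixture sizes; an explicitly supplied
#' `base_channels` is never altered.
#'
#' @param ocs output-channel scale multiplier applied to `base_channels`.
#' @param n_steps number of internal passes (>= 1); each adds one
#'   identically-shaped convolution per block.
#' @param n_stages number of external stages (1 or 2).
#' @param base_channels per-level output channels, shallow to deep.
#' @param in_channels input image channels.
#' @param n_classes 1 for binary masks; for multi-class tasks the number
#'   of labels including background.
#' @param input_size spatial side length; must be divisible by
#'   `2^(depth - 1)`.
#' @param fuse_all_stages logical; fuse the pre-activations of all stages
#'   (default) or of all but the last.
#' @return An object of class `plnet_config`.
#' @examples
#' cfg <- plnet_config()
#' cfg$channels
#' @export
plnet_config <- function(ocs = 1, n_steps = 2L, n_stages = 2L,
                         base_channels = NULL,
                         in_channels = 3L, n_classes = 1L,
                         input_size = 224L, fuse_all_stages = TRUE) {
  if (is.null(base_channels)) {
    base_channels <- c(32L, 64L, 128L, 256L, 512L)
    if (input_size < 128) {
      base_channels <- base_channels[1:4]
      message("input_size < 128: reducing to a four-level channel plan")
    }
  }
  n_steps <- as.integer(n_steps); n_stages <- as.integer(n_stages)
  if (n_steps < 1L) stop("`n_steps` must be >= 1")
  if (!n_stages %in% c(1L, 2L)) stop("`n_stages` must be 1 or 2")
  if (length(base_channels) < 3L)
    stop("the channel plan needs at least three levels")
  ch <- scale_channels(base_channels, ocs)
  depth <- length(ch)
  if (input_size %% 2^(depth - 1) != 0)
    stop(sprintf("`input_size` (%d) must be divisible by 2^(depth-1) = %d",
                 input_size, 2^(depth - 1)))
  if (n_classes < 1L) stop("`n_classes` must be >= 1")
  structure(list(
    ocs = ocs, n_steps = n_steps, n_stages = n_stages,
    base_channels = as.integer(base_channels), channels = ch,
    in_channels = as.integer(in_channels), n_classes = as.integer(n_classes),
    input_size = as.integer(input_size),
    fuse_all_stages = isTRUE(fuse_all_stages)
  ), class = "plnet_config")
}

#' @export
print.plnet_config <- function(x, ...) {
  cat("PL-Net configuration\n")
  cat(sprintf("  channels:  %s (ocs = %g)\n", paste(x$channels, collapse = "-"), x$ocs))
  cat(sprintf("  steps: %d   stages: %d   classes: %d   input: %d^2 x %d\n",
              x$n_steps, x$n_stages, x$n_classes, x$input_size, x$in_channels))
  invisible(x)
}

# config <-> plain list (YAML round-trip)
config_to_list <- function(cfg) unclass(cfg)
config_from_list <- function(lst) {
  plnet_config(
    ocs = lst$ocs %||% 1, n_steps = lst$n_steps %||% 2L,
    n_stages = lst$n_stages %||% 2L,
    base_channels = lst$base_channels,
    in_channels = lst$in_channels %||% 3L,
    n_classes = lst$n_classes %||% 1L,
    input_size = lst$input_size %||% 224L,
    fuse_all_stages = lst$fuse_all_stages %||% TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
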