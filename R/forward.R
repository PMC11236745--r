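# Forward execution: internal progressive learning (IPL) passes with
# forward and backward skip connections.

conv_unit_fwd <- function(tape, model, name, x, training, use = 1L) {
  u <- model$params[[name]]
  W <- tp_leaf(tape, u$W, paste0(name, ".W"))
  g <- tp_leaf(tape, u$g, paste0(name, ".g"))
  be <- tp_leaf(tape, u$be, paste0(name, ".be"))
  # the conv bias is absorbed by the following normalization (its shift
  # is learned through the BN beta); it stays in the parameter count
  # under the documented convention but is not applied or trained
  h <- op_conv3(tape, x, W, NULL)
  # a block reused by several passes/stages sees a different feature
  # distribution on each use; running statistics are therefore kept per
  # invocation (recurrent-BN style), while scale/shift stay shared
  h <- op_bn(tape, h, g, be, training, model$bn_stats,
             paste0(name, "@", use))
  op_relu(tape, h)
}

up_fwd <- function(tape, model, d, x) {
  u <- model$params[[sprintf("up%d", d)]]
  W <- tp_leaf(tape, u$W, sprintf("up%d.W", d))
  b <- tp_leaf(tape, u$b, sprintf("up%d.b", d))
  op_tconv2(tape, x, W, b)
}

head_fwd <- function(tape, model, stage, x) {
  u <- model$params[[sprintf("head%d", stage)]]
  W <- tp_leaf(tape, u$W, sprintf("head%d.W", stage))
  b <- tp_leaf(tape, u$b, sprintf("head%d.b", stage))
  op_conv1(tape, x, W, b)
}

# Internal tensors are laid out (H, W, N, C); these helpers convert the
# package's public (H, W, C) / (H, W, C, N) arrays at the boundary.
to_internal <- function(image) {
  d <- dim(image)
  if (length(d) == 3L) { dim(image) <- c(d[1], d[2], 1L, d[3]); image }
  else aperm(image, c(1, 2, 4, 3))
}
from_internal <- function(x, single) {
  d <- dim(x)
  if (single) { dim(x) <- c(d[1], d[2], d[4]); x }
  else aperm(x, c(1, 2, 4, 3))
}

zeros_like_ch <- function(tape, ref, ch) {
  d <- dim(nd_val(ref))
  tp_node(tape, array(0, c(d[1], d[2], d[3], ch)))
}

# Full progressive forward: runs stages 1..upto_stage, each stage
# executing n_steps complete encode-decode passes whose backward skip
# features are the previous pass's decoder outputs (zeros on the very
# first pass; carried across the stage boundary so stage 2's first pass
# consumes stage 1's final decoder features).
plnet_graph <- function(model, x, tape = NULL, training = FALSE,
                        upto_stage = model$config$n_stages) {
  cfg <- model$config
  ch <- cfg$channels; L <- length(ch); ns <- cfg$n_steps
  if (is.numeric(x)) x <- tp_node(tape, x)
  dims <- dim(nd_val(x))
  if (dims[1] %% 2^(L - 1) != 0 || dims[2] %% 2^(L - 1) != 0)
    stop(sprintf("input spatial dims (%dx%d) must be divisible by 2^(depth-1) = %d",
                 dims[1], dims[2], 2^(L - 1)))
  if (upto_stage < 1L || upto_stage > cfg$n_stages)
    stop("`stage` out of range")
  B <- NULL      # backward features: previous pass's decoder outputs per level
  preacts <- vector("list", upto_stage)
  uses <- new.env(parent = emptyenv())
  cuf <- function(name, x) {
    k <- (uses[[name]] %||% 0L) + 1L
    uses[[name]] <- k
    conv_unit_fwd(tape, model, name, x, training, use = k)
  }
  for (stage in seq_len(upto_stage)) {
    is_last <- stage == cfg$n_stages
    top_enc <- if (is_last) L else L - 1L
    dec_top <- top_enc - 1L
    dec_out <- NULL
    for (s in seq_len(ns)) {
      enc_out <- vector("list", L)
      back <- function(d, ref) {
        if (!is.null(B) && length(B) >= d && !is.null(B[[d]])) B[[d]]
        else zeros_like_ch(tape, ref, ch[d])
      }
      h <- op_concat(tape, list(x, back(1L, x)))
      enc_out[[1L]] <- cuf(sprintf("enc1_s%d", s), h)
      for (d in 2:(L - 1L)) {
        h <- op_maxpool2(tape, op_concat(tape, list(enc_out[[d - 1L]], back(d - 1L, enc_out[[d - 1L]]))))
        enc_out[[d]] <- cuf(sprintf("enc%d_s%d", d, s), h)
      }
      if (is_last) {
        h <- op_maxpool2(tape, enc_out[[L - 1L]])
        h <- cuf("bott_entry", h)
        h <- cuf(sprintf("enc%d_s%d", L, s), h)
        bottom <- cuf("bott_refine", h)
      } else {
        bottom <- cuf("s1_refine", enc_out[[L - 1L]])
      }
      below <- bottom
      dec_out <- vector("list", dec_top)
      for (d in seq.int(dec_top, 1L)) {
        upn <- up_fwd(tape, model, d, below)
        h <- op_concat(tape, list(enc_out[[d]], upn))
        h <- cuf(sprintf("dec%d_s%d", d, s), h)
        dec_out[[d]] <- cuf(sprintf("decr%d", d), h)
        below <- dec_out[[d]]
      }
      B <- dec_out
    }
    preacts[[stage]] <- head_fwd(tape, model, stage, dec_out[[1L]])
  }
  preacts
}

#' Internal-progressive-learning forward pass for one stage
#'
#' Executes all internal passes of stages `1..stage` (stage 2's first
#' pass consumes stage 1's decoder features through the backward skip
#' connections) and returns the requested stage's pre-activation
#' prediction map.
#'
#' @param model a `plnet_model`.
#' @param image array `H x W x C` (single image) or `H x W x C x N`.
#' @param stage stage index in `1..n_stages`.
#' @param training logical; use batch statistics (and update running
#'   statistics) in the normalization layers.
#' @return Pre-activation map with the input's spatial dims and
#'   `n_classes` channels (batch dim kept only for 4D input).
#' @export
ipl_forward <- function(model, image, stage = model$config$n_stages,
                        training = FALSE) {
  single <- length(dim(image)) == 3L
  pre <- plnet_graph(model, to_internal(image), tape = NULL,
                     training = training, upto_stage = stage)
  from_internal(nd_val(pre[[stage]]), single)
}

#' Forward-skip merge: concatenate and convolve same-scale features
#'
#' The classical U-Net skip: the encoder feature `x` and the up-sampled
#' decoder feature `x_hat` at the same scale are concatenated channel-wise
#' and passed through the level's step-`step` decoder conv unit
#' (conv 3x3, batch norm, ReLU).
#'
#' @param model a `plnet_model`.
#' @param x encoder feature, `H x W x ch[level]`.
#' @param x_hat up-sampled decoder feature with the same dims as `x`.
#' @param level decoder level index (1 = finest).
#' @param step step index in `1..n_steps`.
#' @return Merged feature map, `H x W x ch[level]`.
#' @export
fsc_merge <- function(model, x, x_hat, level, step) {
  if (!identical(dim(x)[1:2], dim(x_hat)[1:2]))
    stop("`x` and `x_hat` must share spatial dims")
  single <- length(dim(x)) == 3L
  h <- op_concat(NULL, list(tp_node(NULL, to_internal(x)),
                            tp_node(NULL, to_internal(x_hat))))
  out <- nd_val(conv_unit_fwd(NULL, model, sprintf("dec%d_s%d", level, step), h, FALSE))
  from_internal(out, single)
}

#' Backward-skip merge: inject a previous pass's decoder feature
#'
#' Concatenates the running feature `x` with the same-scale backward
#' feature `prev` (the previous pass's — or, at a stage boundary, the
#' previous stage's — decoder output), pools the result when `level > 1`,
#' and applies the level's step-`step` encoder conv unit. For the very
#' first pass (step 1 of stage 1) no backward feature exists and the
#' backward slot is filled with zeros; passing `prev = NULL` anywhere
#' else is a contract violation.
#'
#' @param model a `plnet_model`.
#' @param x incoming feature at the scale above `level` (the image for
#'   `level = 1`).
#' @param prev same-scale decoder feature from the previous pass, or
#'   `NULL` only for (step 1, stage 1).
#' @param level encoder level the merged feature enters.
#' @param step step index.
#' @param stage stage index.
#' @return The level's encoder output.
#' @export
bsc_merge <- function(model, x, prev, level, step, stage) {
  ch <- model$config$channels
  if (is.null(prev) && !(step == 1L && stage == 1L))
    stop("`prev` may be NULL only for step 1 of stage 1")
  single <- length(dim(x)) == 3L
  xi <- to_internal(x)
  if (is.null(prev)) {
    want <- if (level == 1L) ch[1L] else ch[level - 1L]
    pi_ <- array(0, c(dim(xi)[1:3], want))
  } else {
    if (!identical(dim(prev)[1:2], dim(x)[1:2]))
      stop("`x` and `prev` must share spatial dims")
    pi_ <- to_internal(prev)
  }
  h <- op_concat(NULL, list(tp_node(NULL, xi), tp_node(NULL, pi_)))
  if (level > 1L) h <- op_maxpool2(NULL, h)
  out <- nd_val(conv_unit_fwd(NULL, model, sprintf("enc%d_s%d", level, step), h, FALSE))
  from_internal(out, single)
}
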