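# External progressive learning: per-stage Dice losses, two-phase
# (coarse-to-fine) optimization, equal-weight fusion, prediction.

#' Soft Dice loss
#'
#' `1 - (2|p \* t| + eps) / (|p| + |t| + eps)` with `|.|` the sum over all
#' pixels and the intersection the elementwise product. Zero for perfect
#' overlap, one for disjoint maps (up to the smoothing constant), and
#' differentiable in the predicted probabilities.
#'
#' @param pred_prob probability map, values in `[0, 1]`.
#' @param truth binary map of the same shape, values in `{0, 1}`.
#' @param eps smoothing constant added to numerator and denominator.
#' @return Scalar loss in `[0, 1]`.
#' @examples
#' dice_loss(c(1, 1, 0, 0), c(0, 1, 1, 0))  # 2 px each, 1 shared -> 0.5
#' @export
dice_loss <- function(pred_prob, truth, eps = 1e-6) {
  if (!identical(dim(pred_prob) %||% length(pred_prob),
                 dim(truth) %||% length(truth)))
    stop("`pred_prob` and `truth` must have identical shape")
  if (any(pred_prob < 0 | pred_prob > 1)) stop("`pred_prob` must lie in [0, 1]")
  if (!all(truth %in% c(0, 1))) stop("`truth` must be binary (one-hot encode multi-class masks)")
  s <- sum(pred_prob * truth)
  1 - (2 * s + eps) / (sum(pred_prob) + sum(truth) + eps)
}

#' Fuse per-stage pre-activation maps into probabilities
#'
#' The stage outputs are combined with equal weight: the fused
#' probability is the logistic of the unweighted sum of the stage
#' pre-activations (softmax of the per-class sums when the maps have
#' more than one channel).
#'
#' @param preacts list of per-stage pre-activation arrays with identical
#'   dims (`H x W x n_classes` or with a batch dim).
#' @param fuse_all_stages fuse all stages (default) or all but the last.
#' @return Probability array with the same dims as one pre-activation map.
#' @examples
#' fuse_stage_outputs(list(array(0.3, c(2, 2, 1)), array(0.5, c(2, 2, 1))))[1, 1, 1]
#' # logistic(0.8)
#' @export
fuse_stage_outputs <- function(preacts, fuse_all_stages = TRUE) {
  if (length(preacts) == 0L) stop("`preacts` must hold at least one stage output")
  if (!fuse_all_stages && length(preacts) > 1L)
    preacts <- preacts[seq_len(length(preacts) - 1L)]
  s <- Reduce(`+`, preacts)
  nd <- dim(s)
  K <- if (length(nd) >= 3L) nd[3] else 1L
  if (K == 1L) return(1 / (1 + exp(-s)))
  single <- length(nd) == 3L
  out <- nd_val(op_softmax(NULL, tp_node(NULL, to_internal(s))))
  from_internal(out, single)
}

#' Training/optimization settings
#'
#' Defaults follow common practice for Dice-loss segmentation training:
#' Adam with first-moment decay 0.9, fixed learning rate `1e-4`, batch
#' size 16, early stopping when the validation loss sets no new minimum
#' for `patience` epochs. `phase1_epochs` is the coarse phase in which
#' only the first stage is optimized; it defaults to a quarter of
#' `max_epochs`.
#'
#' @param learning_rate Adam step size.
#' @param batch_size samples per gradient step.
#' @param max_epochs training epoch budget.
#' @param patience early-stopping patience, in epochs.
#' @param beta1,beta2 Adam moment decays.
#' @param phase1_epochs epochs of stage-1-only training before all
#'   stages are optimized jointly; `NULL` for `ceiling(max_epochs / 4)`.
#' @param seed RNG seed controlling shuffling (and any augmentation).
#' @param augment apply random geometric augmentation to each training
#'   batch (see [augment_sample()]).
#' @param stop_loss optional convergence target: training also stops
#'   once the monitored loss falls at or below this value.
#' @return An object of class `plnet_run_config`.
#' @export
run_config <- function(learning_rate = 1e-4, batch_size = 16L,
                       max_epochs = 200L, patience = 20L,
                       beta1 = 0.9, beta2 = 0.999,
                       phase1_epochs = NULL, seed = 1L, augment = FALSE,
                       stop_loss = 0) {
  if (learning_rate <= 0 || batch_size < 1 || max_epochs < 1 || patience < 1)
    stop("learning_rate, batch_size, max_epochs and patience must be positive")
  if (patience >= max_epochs) stop("`patience` must be smaller than `max_epochs`")
  if (is.null(phase1_epochs)) phase1_epochs <- ceiling(max_epochs / 4)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 beta1 = beta1, beta2 = beta2,
                 phase1_epochs = as.integer(phase1_epochs),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 stop_loss = stop_loss),
            class = "plnet_run_config")
}

# stack a list of seg_samples into internal-layout (H,W,N,C) images and
# (H,W,N,K) one-hot targets
stack_batch <- function(samples, n_classes) {
  N <- length(samples)
  d <- dim(samples[[1]]$image)
  X <- array(0, c(d[1], d[2], N, d[3]))
  K <- max(1L, n_classes)
  TT <- array(0, c(d[1], d[2], N, K))
  for (i in seq_len(N)) {
    X[, , i, ] <- samples[[i]]$image
    msk <- samples[[i]]$mask
    if (K == 1L) TT[, , i, 1L] <- as.numeric(msk > 0)
    else for (k in seq_len(K)) TT[, , i, k] <- as.numeric(msk == (k - 1L))
  }
  list(x = X, truth = TT)
}

# taped per-stage Dice losses; multi-class averages the per-class soft
# Dice over the foreground classes.
stage_losses <- function(tape, preacts, truth, n_classes) {
  lapply(preacts, function(y) {
    if (n_classes == 1L) {
      op_dice(tape, op_sigmoid(tape, y), truth)
    } else {
      p <- op_softmax(tape, y)
      cls <- 2:n_classes
      ls <- lapply(cls, function(k) {
        pk <- tp_node(tape, nd_val(p)[, , , k, drop = FALSE],
                      ins = nd_id(p), back = local({
                        kk <- k
                        function(g) {
                          gp <- array(0, dim(nd_val(p)))
                          gp[, , , kk] <- g
                          list(gp)
                        }
                      }))
        op_dice(tape, pk, truth[, , , k, drop = FALSE])
      })
      op_wsum(tape, ls, rep(1 / length(ls), length(ls)))
    }
  })
}

adam_step <- function(model, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    blk <- parts[1]; fld <- parts[2]
    m <- state$m[[nm]]; v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    state$m[[nm]] <- m; state$v[[nm]] <- v
    mhat <- m / (1 - b1^t); vhat <- v / (1 - b2^t)
    model$params[[blk]][[fld]] <- model$params[[blk]][[fld]] - lr * mhat / (sqrt(vhat) + eps)
  }
  model
}

#' Train PL-Net with external progressive learning
#'
#' Phase 1 optimizes the Dice loss of the first stage's prediction only;
#' phase 2 optimizes the equal-weight mean of all stages' Dice losses
#' with every parameter trainable (stage 1 is not frozen). Validation
#' loss is monitored each epoch and training stops early when no new
#' minimum has been seen for `patience` epochs; the returned model
#' carries the best-on-validation weights.
#'
#' @param model a `plnet_model` (freshly built or warm).
#' @param train_set,val_set lists of `seg_sample` objects; `val_set` may
#'   be `NULL`, in which case the training loss is monitored instead.
#' @param config a [run_config()].
#' @param verbose print a line per epoch.
#' @return An object of class `plnet_fit`: `model` (best weights),
#'   `history` (one row per epoch: phase, per-stage and total training
#'   loss, monitored loss), and `best_epoch`.
#' @export
train_epl <- function(model, train_set, val_set = NULL, config = run_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "plnet_model"), inherits(config, "plnet_run_config"))
  if (length(train_set) == 0L) stop("`train_set` is empty")
  set.seed(config$seed)
  K <- model$config$n_classes
  nst <- model$config$n_stages
  state <- new.env(parent = emptyenv())
  state$t <- 0L; state$m <- list(); state$v <- list()
  n <- length(train_set)
  hist <- vector("list", config$max_epochs)
  best <- Inf; best_params <- NULL; best_stats <- NULL; best_epoch <- NA_integer_
  stale <- 0L
  has_val <- length(val_set) > 0L
  for (epoch in seq_len(config$max_epochs)) {
    phase <- if (nst > 1L && epoch <= config$phase1_epochs) 1L else 2L
    upto <- if (phase == 1L) 1L else nst
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_stage <- numeric(nst); ep_tot <- 0; wsum <- 0
    for (bi in batches) {
      smp <- train_set[bi]
      if (config$augment) {
        smp <- lapply(smp, augment_sample)
      }
      bt <- stack_batch(smp, K)
      tape <- new_tape()
      pre <- plnet_graph(model, bt$x, tape = tape, training = TRUE, upto_stage = upto)
      ls <- stage_losses(tape, pre, bt$truth, K)
      total <- op_wsum(tape, ls, rep(1 / length(ls), length(ls)))
      if (!is.finite(nd_val(total)))
        stop(sprintf("non-finite loss at epoch %d; aborting", epoch))
      tape_backward(tape, total)
      model <- adam_step(model, tape$param_grads, state,
                         config$learning_rate, config$beta1, config$beta2)
      w <- length(bi)
      ep_stage[seq_len(upto)] <- ep_stage[seq_len(upto)] +
        w * vapply(ls, nd_val, numeric(1))
      ep_tot <- ep_tot + w * nd_val(total); wsum <- wsum + w
    }
    ep_stage <- ep_stage / wsum; ep_tot <- ep_tot / wsum
    if (upto < nst) ep_stage[(upto + 1L):nst] <- NA_real_
    mon <- if (has_val) monitor_loss(model, val_set, upto) else ep_tot
    row <- data.frame(epoch = epoch, phase = phase, total = ep_tot,
                      monitored = mon)
    for (sg in seq_len(nst)) row[[sprintf("stage%d", sg)]] <- ep_stage[sg]
    hist[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d phase %d  train %.4f  monitored %.4f",
                      epoch, phase, ep_tot, mon))
    if (mon < best) {
      best <- mon; best_epoch <- epoch; stale <- 0L
      best_params <- model$params
      best_stats <- as.list(model$bn_stats)
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
    if (phase == 2L && mon <= config$stop_loss) break
  }
  if (!is.null(best_params)) {
    model$params <- best_params
    rm(list = ls(model$bn_stats), envir = model$bn_stats)
    for (nm in names(best_stats)) model$bn_stats[[nm]] <- best_stats[[nm]]
  }
  structure(list(model = model,
                 history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
                 best_epoch = best_epoch, best_loss = best),
            class = "plnet_fit")
}

# mean total Dice loss over a sample list, eval mode, no gradient
monitor_loss <- function(model, samples, upto) {
  K <- model$config$n_classes
  bt <- stack_batch(samples, K)
  pre <- plnet_graph(model, bt$x, tape = NULL, training = FALSE, upto_stage = upto)
  ls <- stage_losses(NULL, pre, bt$truth, K)
  mean(vapply(ls, nd_val, numeric(1)))
}

#' @export
print.plnet_fit <- function(x, ...) {
  cat(sprintf("PL-Net fit: %d epochs, best monitored loss %.4f at epoch %d\n",
              nrow(x$history), x$best_loss, x$best_epoch))
  invisible(x)
}

#' Predict a segmentation for one image
#'
#' Runs every stage's forward pass, fuses the pre-activation maps with
#' [fuse_stage_outputs()] (the per-stage sigmoid prediction layers are
#' never materialized), and thresholds at 0.5 (binary) or takes the
#' per-pixel argmax (multi-class).
#'
#' @param object a `plnet_model` or `plnet_fit`.
#' @param image preprocessed image, `H x W x in_channels`, values in
#'   `[0, 1]`.
#' @param ... unused.
#' @return list with `prob` (fused probability map, `H x W` or
#'   `H x W x n_classes`) and `labels` (`H x W` integer map).
#' @export
predict.plnet_model <- function(object, image, ...) {
  model <- object
  K <- model$config$n_classes
  if (length(dim(image)) != 3L)
    stop("`image` must be a single H x W x C array")
  pre <- plnet_graph(model, to_internal(image), tape = NULL, training = FALSE)
  pre <- lapply(pre, function(p) from_internal(nd_val(p), TRUE))
  prob <- fuse_stage_outputs(pre, model$config$fuse_all_stages)
  if (K == 1L) {
    prob2 <- prob[, , 1L]
    labels <- matrix(as.integer(prob2 >= 0.5), nrow(prob2), ncol(prob2))
    list(prob = prob2, labels = labels)
  } else {
    labels <- apply(prob, c(1, 2), which.max) - 1L
    list(prob = prob, labels = labels)
  }
}

#' @export
predict.plnet_fit <- function(object, image, ...) predict(object$model, image, ...)
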