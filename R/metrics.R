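# Segmentation metrics: one-vs-rest confusion counts and the five
# reported scores (accuracy, IoU, Dice, sensitivity, specificity).

#' One-vs-rest confusion counts for a class
#'
#' @param pred_labels,truth_labels integer label maps of equal shape.
#' @param class_id the class evaluated one-vs-rest.
#' @return list with `tp`, `fp`, `tn`, `fn` (and the class id), class
#'   `confusion_counts`.
#' @export
confusion <- function(pred_labels, truth_labels, class_id) {
  if (!identical(dim(pred_labels), dim(truth_labels)))
    stop("prediction and truth must have identical shape")
  p <- pred_labels == class_id
  t <- truth_labels == class_id
  structure(list(class_id = class_id,
                 tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' The five segmentation scores from confusion counts
#'
#' `acc = (tp+tn)/total`, `iou = tp/(tp+fp+fn)`,
#' `dice = 2tp/(2tp+fp+fn)`, `sens = tp/(tp+fn)`, `spec = tn/(tn+fp)`.
#' A score whose denominator is zero is 1 when the class is absent from
#' both maps (nothing to find, nothing found) and 0 otherwise.
#'
#' @param counts a `confusion_counts` (or any list with tp/fp/tn/fn).
#' @return Named numeric vector `acc, iou, dice, sens, spec`.
#' @export
metric_suite <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  absent_both <- (tp + fn == 0) && (tp + fp == 0)
  safe <- function(num, den) if (den > 0) num / den else if (absent_both) 1 else 0
  c(acc = (tp + tn) / (tp + fp + tn + fn),
    iou = safe(tp, tp + fp + fn),
    dice = safe(2 * tp, 2 * tp + fp + fn),
    sens = safe(tp, tp + fn),
    spec = if (tn + fp > 0) tn / (tn + fp) else if (absent_both) 1 else 0)
}

#' Evaluate a model (or repeated runs) on a sample list
#'
#' Metrics are computed per image and per foreground class, then
#' averaged over images (per-image averaging matches mean-and-deviation
#' reporting; set `pooled = TRUE` to pool confusion counts over all
#' images instead). For multi-class tasks the report has one row per
#' foreground class plus their unweighted average; across several models
#' (independent training runs) it reports mean and sample standard
#' deviation of every score.
#'
#' @param model a `plnet_model`/`plnet_fit`, or a list of them (one per
#'   run).
#' @param samples list of preprocessed `seg_sample` objects.
#' @param n_runs number of runs expected; defaults to the number of
#'   models supplied.
#' @param pooled pool confusion counts over images instead of averaging
#'   per-image scores.
#' @return An object of class `plnet_eval_report`: data frame `scores`
#'   (columns class, acc, iou, dice, sens, spec, and `*_sd` when
#'   `n_runs > 1`) and the evaluation settings.
#' @export
evaluate_model <- function(model, samples, n_runs = NULL, pooled = FALSE) {
  models <- if (inherits(model, c("plnet_model", "plnet_fit"))) list(model) else model
  models <- lapply(models, function(m) if (inherits(m, "plnet_fit")) m$model else m)
  if (is.null(n_runs)) n_runs <- length(models)
  if (n_runs != length(models))
    stop("`n_runs` must match the number of models supplied")
  K <- models[[1]]$config$n_classes
  cls <- if (K == 1L) 1L else seq_len(K - 1L)
  cls_names <- if (K == 1L) "foreground" else {
    cn <- samples[[1]]$class_names
    if (!is.null(cn) && length(cn) >= K) cn[cls + 1L] else paste0("class", cls)
  }
  run_scores <- lapply(models, function(m) {
    per_image <- lapply(samples, function(s) {
      pred <- predict(m, s$image)$labels
      vapply(cls, function(k) {
        if (pooled) unlist(confusion(pred, s$mask, k)[c("tp", "fp", "tn", "fn")])
        else metric_suite(confusion(pred, s$mask, k))
      }, numeric(if (pooled) 4L else 5L))
    })
    if (pooled) {
      tot <- Reduce(`+`, per_image)   # 4 x n_cls matrix of pooled counts
      out <- vapply(seq_along(cls), function(j)
        metric_suite(as.list(stats::setNames(tot[, j], c("tp", "fp", "tn", "fn")))),
        numeric(5L))
    } else {
      out <- Reduce(`+`, per_image) / length(per_image)
    }
    t(out)    # n_cls x 5
  })
  mean_mat <- Reduce(`+`, run_scores) / n_runs
  scores <- data.frame(class = cls_names, mean_mat, check.names = FALSE)
  if (K > 1L)
    scores <- rbind(scores, data.frame(class = "average",
                                       t(colMeans(mean_mat)), check.names = FALSE))
  if (n_runs > 1L) {
    sd_mat <- sqrt(Reduce(`+`, lapply(run_scores, function(s) (s - mean_mat)^2)) / (n_runs - 1))
    if (K > 1L) sd_mat <- rbind(sd_mat, t(colMeans(sd_mat)))
    colnames(sd_mat) <- paste0(colnames(mean_mat), "_sd")
    scores <- cbind(scores, sd_mat)
  }
  rownames(scores) <- NULL
  structure(list(scores = scores, n_runs = n_runs, pooled = pooled,
                 n_images = length(samples)),
            class = "plnet_eval_report")
}

#' @export
print.plnet_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d image(s), %d run(s)%s\n", x$n_images,
              x$n_runs, if (x$pooled) ", pooled counts" else ""))
  print(x$scores, digits = 4, row.names = FALSE)
  invisible(x)
}
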