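# Model checkpointing: one serialized weights file plus a YAML sidecar
# echoing the architecture, so downstream commands never guess the
# topology.

#' Save / load a model checkpoint
#'
#' `save_checkpoint()` writes the parameters and batch-norm running
#' statistics to `path` and the architecture configuration to
#' `<path>.yaml`; `load_checkpoint()` rebuilds the model from them.
#'
#' @param model a `plnet_model` or `plnet_fit`.
#' @param path checkpoint file path (e.g. `model.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the restored `plnet_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "plnet_fit")) model <- model$model
  stopifnot(inherits(model, "plnet_model"))
  saveRDS(list(params = model$params, bn_stats = as.list(model$bn_stats),
               config = config_to_list(model$config)), path)
  yaml::write_yaml(config_to_list(model$config), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- config_from_list(obj$config)
  model <- structure(list(config = cfg, params = obj$params,
                          bn_stats = new.env(parent = emptyenv())),
                     class = "plnet_model")
  for (nm in names(obj$bn_stats)) model$bn_stats[[nm]] <- obj$bn_stats[[nm]]
  model
}
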