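# YAML run-configuration and checkpoint helpers.

#' Read a run configuration file
#'
#' One flat YAML file with optional sections `scene`, `model`, `train`;
#' fields mirror [scene_spec()], [model_config()] and [train_config()]
#' arguments field-for-field. Missing sections fall back to defaults.
#'
#' @param path YAML file.
#' @return List with `scene`, `model`, `train` objects.
#' @export
read_run_config <- function(path) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  list(scene = do.call(scene_spec, y$scene %||% list()),
       model = do.call(model_config, y$model %||% list()),
       train = do.call(train_config, y$train %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' A checkpoint is the flat named-parameter container together with the
#' batch-norm state and the architectural configuration, so a loaded model
#' is immediately usable for inference.
#'
#' @param model model list (params/state/cfg).
#' @param path checkpoint path (`.rds`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the model list.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model[c("params", "state", "cfg")], path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!all(c("params", "state", "cfg") %in% names(m)))
    stop_format("not a model checkpoint: ", path)
  m
}
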