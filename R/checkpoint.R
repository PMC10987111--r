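#' Save and load trained models
#'
#' A checkpoint is a single archive holding the layer weights, both
#' configurations, the atom-feature schema version, the frozen label
#' normalizer, the training seed and a format-version string. A round trip
#' reproduces predictions bit-identically; loading a file with an unknown
#' format or schema raises an explicit error rather than returning garbage.
#'
#' @param model A `gat_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gat_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop_bk(sprintf("Checkpoint '%s' does not exist.", path),
            "bkscore_io_error")
  }
  m <- tryCatch(readRDS(path), error = function(e) {
    stop_bk(sprintf("Checkpoint '%s' is corrupted or not a checkpoint: %s",
                    path, conditionMessage(e)), "bkscore_io_error")
  })
  if (!inherits(m, "gat_model") ||
      !identical(m$format_version, "bkscore-checkpoint-1")) {
    stop_bk(sprintf("'%s' is not a recognized model checkpoint.", path),
            "bkscore_io_error")
  }
  tryCatch(feature_schema(m$schema_version), error = function(e) {
    stop_bk(sprintf(
      "Checkpoint uses feature schema '%s', unknown to this version.",
      m$schema_version), "bkscore_incompatible")
  })
  m
}
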