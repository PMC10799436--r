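#' Save a model checkpoint
#'
#' Serializes the whole model (configurations, all parameters, batch-norm
#' running moments) together with a JSON metadata header describing the
#' architecture.
#'
#' @param model an `adfuse_model`.
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  meta <- list(package = "adfuse",
               ablation = model$fus_cfg$ablation,
               input_edge = model$input_edge,
               n_feature_maps = model$enc_cfg$final_filters,
               token_dim = model$token_dim,
               n_params = n_params(model),
               saved = format(Sys.time(), tz = "UTC"))
  obj <- list(meta_json = jsonlite::toJSON(meta, auto_unbox = TRUE),
              model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return The `adfuse_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$model) || !inherits(obj$model, "adfuse_model"))
    stop(sprintf("load_checkpoint: '%s' is not an adfuse checkpoint", path))
  obj$model
}
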