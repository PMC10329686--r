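# Model checkpoints: one binary RDS per model plus a JSON sidecar recording
# the version tag, class, and hyperparameters, so a checkpoint is
# inspectable without loading it. Checkpoints are runtime artifacts, never
# shipped with the package.

#' Save / load a trained model checkpoint
#'
#' @param model a `LocationModel` or `AugmenterModel`.
#' @param path checkpoint file (`.rds`); a `<path>.json` sidecar with the
#'   version tag and configuration is written next to it.
#' @return `save_checkpoint`: `path` invisibly. `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("LocationModel", "AugmenterModel")))
  saveRDS(model, path)
  side <- list(format = "spotloc-checkpoint-v1",
               class = class(model)[1L],
               package_version = as.character(packageVersion("spotloc")),
               config = if (inherits(model, "LocationModel"))
                 unclass(model$config) else unclass(model$config))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("LocationModel", "AugmenterModel")))
    stop(path, " is not a spotloc checkpoint", call. = FALSE)
  model
}
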