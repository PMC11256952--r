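#' Save or load a model checkpoint
#'
#' A checkpoint is a single archive holding every parameter tensor, the
#' canonical gene ordering, the configuration and the PPI prior that was
#' used, so a model is loadable without the original edge list.  Both
#' perturbation models (`csg2a_model`) and fine-tuned drug-response models
#' (`csg2a_drm`) are supported.
#'
#' @param model A `csg2a_model` or `csg2a_drm`.
#' @param path Checkpoint path (RDS archive, written at run time).
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("csg2a_model", "csg2a_drm")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("csg2a_model", "csg2a_drm")))
    stop("not a csg2a checkpoint: ", path)
  model
}
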