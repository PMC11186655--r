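#' Save and load parameter checkpoints
#'
#' Parameters (encoder, projection head, classifier head) are stored as a
#' key -> tensor container (RDS of the nested parameter list) together with
#' a JSON manifest listing the shape of every tensor, so checkpoints can be
#' inspected without loading them.
#'
#' @param params A parameter list (`encoder_params`, `projection_params`,
#'   `deep_mlp_params`, ...).
#' @param path File path for the checkpoint (the manifest is written next
#'   to it as `<path>.manifest.json`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the parameter list.
#' @export
save_checkpoint <- function(params, path) {
  manifest <- list()
  walk <- function(p, prefix) {
    if (is.list(p)) {
      for (nm in names(p)) walk(p[[nm]], paste0(prefix, "/", nm))
    } else if (is.numeric(p)) {
      manifest[[sub("^/", "", prefix)]] <<- dim(p) %||% length(p)
    }
  }
  walk(unclass(params), "")
  saveRDS(params, path)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
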