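#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the model parameters together
#' with the encoder configuration and a fingerprint of it; loading verifies
#' the fingerprint so weights can never be silently attached to a different
#' architecture.
#'
#' @param model an \linkS4class{MVModel}.
#' @param path checkpoint file path.
#' @return \code{saveCheckpoint}: \code{path}, invisibly;
#'   \code{loadCheckpoint}: the restored \linkS4class{MVModel}.
#' @export
saveCheckpoint <- function(model, path) {
  cfg <- model@encoderConfig
  obj <- list(format = "mvfusion-checkpoint-1",
              fingerprint = configFingerprint(cfg),
              config = list(stemChannels = cfg@stemChannels,
                            blockChannels = cfg@blockChannels,
                            blocksPerStage = cfg@blocksPerStage,
                            embeddingDim = cfg@embeddingDim),
              viewIds = model@viewIds, strategy = model@strategy,
              params = model@params, trainLog = model@trainLog)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mvfusion-checkpoint-1"))
    stop(sprintf("'%s' is not an mvfusion checkpoint", path))
  cfg <- encoderConfig(obj$config$stemChannels, obj$config$blockChannels,
                       obj$config$blocksPerStage, obj$config$embeddingDim)
  if (!identical(configFingerprint(cfg), obj$fingerprint))
    stop(sprintf(
      "checkpoint '%s': config fingerprint mismatch (%s vs %s)", path,
      configFingerprint(cfg), obj$fingerprint))
  new("MVModel", encoderConfig = cfg, viewIds = obj$viewIds,
      strategy = obj$strategy, params = obj$params, trainLog = obj$trainLog)
}
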