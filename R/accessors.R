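#' Accessors for mvfusion S4 objects
#'
#' Slot access for \linkS4class{ViewVolume}, \linkS4class{MultiViewCase},
#' \linkS4class{DatasetSplit}, \linkS4class{MVModel} and
#' \linkS4class{EvalReport} objects.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("viewId", "ViewVolume", function(x) x@viewId)

#' @rdname accessors
#' @export
setMethod("viewData", "ViewVolume", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("dim", "ViewVolume", function(x) dim(x@voxels))

#' @rdname accessors
#' @export
setMethod("caseId", "MultiViewCase", function(x) x@caseId)

#' @rdname accessors
#' @export
setMethod("caseLabel", "MultiViewCase", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("caseViews", "MultiViewCase", function(x) x@views)

#' @rdname accessors
#' @export
setMethod("nViews", "MultiViewCase", function(x) length(x@views))

#' @rdname accessors
#' @export
setMethod("viewIds", "MultiViewCase",
          function(x) vapply(x@views, viewId, character(1)))

#' @rdname accessors
#' @export
setMethod("nViews", "MVModel", function(x) length(x@viewIds))

#' @rdname accessors
#' @export
setMethod("viewIds", "MVModel", function(x) x@viewIds)

#' @rdname accessors
#' @export
setMethod("fusionStrategy", "MVModel", function(x) x@strategy)

#' @rdname accessors
#' @export
setMethod("trainLog", "MVModel", function(x) x@trainLog)

#' @rdname accessors
#' @export
setMethod("trainCases", "DatasetSplit", function(x) x@train)

#' @rdname accessors
#' @export
setMethod("valCases", "DatasetSplit", function(x) x@validation)

#' @rdname accessors
#' @export
setMethod("testCases", "DatasetSplit", function(x) x@test)

#' @rdname accessors
#' @export
setMethod("auc", "EvalReport", function(x) x@auc)

#' @rdname accessors
#' @export
setMethod("probabilities", "EvalReport", function(x) x@probabilities)

#' @rdname accessors
#' @export
setMethod("operatingPoint", "EvalReport", function(x) {
  c(threshold = x@optimalThreshold, sensitivity = x@sensitivity,
    specificity = x@specificity)
})

setMethod("show", "ViewVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ViewVolume '%s' %d x %d x %d (depth x height x width)\n",
              object@viewId, d[1], d[2], d[3]))
  cat(sprintf("  intensity mean %.4g, sd %.4g\n",
              mean(object@voxels), stats::sd(as.vector(object@voxels))))
})

setMethod("show", "MultiViewCase", function(object) {
  cat(sprintf("MultiViewCase '%s', label %d, %d view(s): %s\n",
              object@caseId, object@label, length(object@views),
              paste(viewIds(object), collapse = ", ")))
})

setMethod("show", "DatasetSplit", function(object) {
  npos <- function(l) sum(vapply(l, caseLabel, integer(1)))
  cat("DatasetSplit\n")
  cat(sprintf("  train:      %3d cases (%d positive)\n",
              length(object@train), npos(object@train)))
  cat(sprintf("  validation: %3d cases (%d positive)\n",
              length(object@validation), npos(object@validation)))
  cat(sprintf("  test:       %3d cases (%d positive)\n",
              length(object@test), npos(object@test)))
})

setMethod("show", "EncoderConfig", function(object) {
  cat(sprintf(
    "EncoderConfig: stem %d ch; stages [%s] x [%s] blocks; embedding %d\n",
    object@stemChannels, paste(object@blockChannels, collapse = "/"),
    paste(object@blocksPerStage, collapse = "/"), object@embeddingDim))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: lr %g, %d epochs, batch %d, beta1 %g, wd %g, seed %d\n",
    object@learningRate, object@epochs, object@batchSize, object@beta1,
    object@weightDecay, object@seed))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d cases, %d views of %s, %.0f%% positive, A=%g, sd=%g\n",
    object@nCases, object@nViews, paste(object@shape, collapse = "x"),
    100 * object@positiveFraction, object@signalAmplitude, object@noiseSd))
})

setMethod("show", "MVModel", function(object) {
  cat(sprintf("MVModel [%s], views: %s\n", object@strategy,
              paste(object@viewIds, collapse = ", ")))
  show(object@encoderConfig)
  if (nrow(object@trainLog))
    cat(sprintf("  trained %d epochs; best val AUC %.4f (epoch %d)\n",
                nrow(object@trainLog), max(object@trainLog$val_auc),
                which.max(object@trainLog$val_auc)))
  else cat("  untrained\n")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d cases (%d positive)\n",
              length(object@labels), sum(object@labels)))
  cat(sprintf("  AUC %.4f; optimal threshold %.4f -> sens %.4f, spec %.4f\n",
              object@auc, object@optimalThreshold, object@sensitivity,
              object@specificity))
})
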