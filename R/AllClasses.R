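#' @useDynLib mvfusion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif
#' @importFrom utils read.csv write.csv
NULL

#' ViewVolume: one view's 3D intensity volume
#'
#' A single acquisition orientation/weighting of one case, stored as a
#' numeric array indexed \code{(depth, height, width)}: depth is the number
#' of slices, height and width the in-plane size. Intensities are arbitrary
#' reals; after \code{\link{preprocessVolume}} they are z-scored (mean 0,
#' sd 1).
#'
#' @slot viewId short tag naming the view, e.g. \code{"sagT1"} or
#'   \code{"axial"}.
#' @slot voxels 3-D numeric array, dim \code{c(depth, height, width)}.
#' @export
setClass("ViewVolume", representation(viewId = "character", voxels = "array"))

setValidity("ViewVolume", function(object) {
  msg <- character()
  if (length(object@viewId) != 1L || !nzchar(object@viewId))
    msg <- c(msg, "viewId must be a single non-empty string")
  d <- dim(object@voxels)
  if (length(d) != 3L)
    msg <- c(msg, sprintf("voxels must be a 3-D array, got %d dimension(s)",
                          length(d)))
  else {
    if (d[1] < 1L) msg <- c(msg, "depth must be >= 1")
    if (d[2] < 8L || d[3] < 8L)
      msg <- c(msg, sprintf("in-plane size must be >= 8, got %d x %d",
                            d[2], d[3]))
  }
  if (!is.numeric(object@voxels))
    msg <- c(msg, "voxels must be numeric")
  if (length(msg)) msg else TRUE
})

#' MultiViewCase: one patient's ordered set of views plus a binary label
#'
#' The label is 1 for the positive class (e.g. ACL tear present) and 0
#' otherwise. View order is canonical and must be identical across all cases
#' of one dataset; it is never inferred from the filesystem.
#'
#' @slot caseId unique case identifier.
#' @slot views list of \linkS4class{ViewVolume} with distinct view ids.
#' @slot label integer 0 or 1.
#' @export
setClass("MultiViewCase",
         representation(caseId = "character", views = "list",
                        label = "integer"))

setValidity("MultiViewCase", function(object) {
  msg <- character()
  if (length(object@caseId) != 1L || !nzchar(object@caseId))
    msg <- c(msg, "caseId must be a single non-empty string")
  if (length(object@views) < 1L)
    msg <- c(msg, "a case needs at least one view")
  if (!all(vapply(object@views, is, logical(1), "ViewVolume")))
    msg <- c(msg, "views must all be ViewVolume objects")
  else {
    ids <- vapply(object@views, function(v) v@viewId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate view_id: %s",
                            paste(ids[duplicated(ids)], collapse = ", ")))
  }
  if (length(object@label) != 1L || !(object@label %in% c(0L, 1L)))
    msg <- c(msg, "label must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' DatasetSplit: train / validation / test partitions
#'
#' @slot train,validation,test lists of \linkS4class{MultiViewCase}. A case
#'   id may appear in at most one partition (no patient overlap).
#' @export
setClass("DatasetSplit",
         representation(train = "list", validation = "list", test = "list"))

setValidity("DatasetSplit", function(object) {
  ids <- c(vapply(object@train, function(x) x@caseId, character(1)),
           vapply(object@validation, function(x) x@caseId, character(1)),
           vapply(object@test, function(x) x@caseId, character(1)))
  if (anyDuplicated(ids))
    sprintf("case id in more than one partition: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  else TRUE
})

#' EncoderConfig: architecture of the shared 3D residual encoder
#'
#' The default configuration is a 3D ResNet-10-style network: a stem
#' (Conv3D 3x3x3 + BN3D + ReLU + MaxPool3D 2x2x2), four stages of one basic
#' residual block each with channel widths 64/128/256/512 (stages 2-4 at
#' stride 2), and adaptive average pooling to a single spatial cell, so the
#' per-view embedding has length \code{embeddingDim} = 512.
#'
#' @slot stemChannels channels produced by the stem convolution.
#' @slot blockChannels channel width of each stage.
#' @slot blocksPerStage number of basic residual blocks per stage.
#' @slot embeddingDim length of the per-view embedding; must equal the last
#'   stage's channel width (the global average pool preserves channels).
#' @export
setClass("EncoderConfig",
         representation(stemChannels = "integer", blockChannels = "integer",
                        blocksPerStage = "integer", embeddingDim = "integer"))

setValidity("EncoderConfig", function(object) {
  msg <- character()
  if (length(object@blockChannels) != length(object@blocksPerStage))
    msg <- c(msg, "blockChannels and blocksPerStage must have equal length")
  if (any(c(object@stemChannels, object@blockChannels,
            object@blocksPerStage, object@embeddingDim) < 1L))
    msg <- c(msg, "all architecture sizes must be positive")
  nstage <- length(object@blockChannels)
  lastC <- if (nstage) object@blockChannels[nstage] else object@stemChannels
  if (object@embeddingDim != lastC)
    msg <- c(msg, sprintf(
      "embeddingDim (%d) must equal the final channel width (%d)",
      object@embeddingDim, lastC))
  if (length(msg)) msg else TRUE
})

#' TrainConfig: optimisation hyperparameters
#'
#' Defaults follow the reference training recipe: Adam with initial learning
#' rate 1e-4, first-moment coefficient (momentum) beta1 = 0.9, weight decay
#' 1e-4, batch size 32, 100 epochs; the snapshot with the best validation
#' AUC is kept.
#'
#' @slot learningRate Adam step size.
#' @slot epochs number of passes over the training partition.
#' @slot batchSize cases per mini-batch (each case contributes all views).
#' @slot beta1,beta2 Adam moment coefficients.
#' @slot weightDecay L2 penalty coefficient added to gradients.
#' @slot posWeight multiplier on the positive-class loss term (1 = off);
#'   an option for imbalanced data.
#' @slot seed RNG seed for initialisation and batch shuffling.
#' @export
setClass("TrainConfig",
         representation(learningRate = "numeric", epochs = "integer",
                        batchSize = "integer", beta1 = "numeric",
                        beta2 = "numeric", weightDecay = "numeric",
                        posWeight = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@beta1 < 0 || object@beta1 >= 1) msg <- c(msg, "beta1 in [0,1)")
  if (object@beta2 < 0 || object@beta2 >= 1) msg <- c(msg, "beta2 in [0,1)")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (object@posWeight <= 0) msg <- c(msg, "posWeight must be > 0")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic multi-view phantom world
#'
#' Phantoms emulate the structural challenge of multi-view diagnosis: the
#' label-dependent signal (an ellipsoidal lesion) is only partially visible
#' in each view, so no single view carries the full evidence and pooling
#' views genuinely helps.
#'
#' @slot nViews number of views per case.
#' @slot shape volume shape \code{c(depth, height, width)}.
#' @slot nCases total number of cases.
#' @slot positiveFraction fraction of positive (lesion-bearing) cases.
#' @slot signalAmplitude peak lesion intensity added over background; 0
#'   yields a null world with no class signal.
#' @slot noiseSd standard deviation of the per-voxel Gaussian noise.
#' @slot viewInformativeness per-view fraction of the lesion's angular
#'   extent that the view renders, each in [0, 1].
#' @slot lesionArc fraction of the full azimuth the lesion itself occupies
#'   (its angular position is drawn per case). 1 = full ellipsoid; smaller
#'   values give a focal tear that only some view windows intersect, so
#'   which views are informative varies from case to case.
#' @slot seed RNG seed; generation is a pure function of (spec, seed).
#' @export
setClass("PhantomSpec",
         representation(nViews = "integer", shape = "integer",
                        nCases = "integer", positiveFraction = "numeric",
                        signalAmplitude = "numeric", noiseSd = "numeric",
                        viewInformativeness = "numeric",
                        lesionArc = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@nViews < 1L) msg <- c(msg, "nViews must be >= 1")
  if (length(object@shape) != 3L || any(object@shape < c(1L, 8L, 8L)))
    msg <- c(msg, "shape must be (depth >= 1, height >= 8, width >= 8)")
  if (object@positiveFraction <= 0 || object@positiveFraction >= 1)
    msg <- c(msg, "positiveFraction must lie in (0, 1)")
  if (object@signalAmplitude < 0) msg <- c(msg, "signalAmplitude must be >= 0")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (length(object@viewInformativeness) != object@nViews)
    msg <- c(msg, "viewInformativeness needs one entry per view")
  if (any(object@viewInformativeness < 0 | object@viewInformativeness > 1))
    msg <- c(msg, "viewInformativeness entries must lie in [0, 1]")
  if (object@lesionArc <= 0 || object@lesionArc > 1)
    msg <- c(msg, "lesionArc must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' MVModel: a weighted multi-view classification model
#'
#' Bundles the shared-weight 3D residual encoder, the view-scoring network
#' that produces softmax view weights, the classifier head, and the fusion
#' strategy. Untrained models are created with \code{\link{mvModel}};
#' \code{\link{trainModel}} returns a trained copy with a populated
#' \code{trainLog}.
#'
#' @slot encoderConfig an \linkS4class{EncoderConfig}.
#' @slot viewIds canonical view order the model was built for.
#' @slot strategy one of \code{"weighted_feature"}, \code{"concat_feature"},
#'   \code{"label_average"}, \code{"label_weighted"}.
#' @slot params list of parameter tensors (encoder, weight net, head).
#' @slot trainLog per-epoch data.frame (epoch, train_loss, val_auc) once
#'   trained.
#' @export
setClass("MVModel",
         representation(encoderConfig = "EncoderConfig", viewIds = "character",
                        strategy = "character", params = "list",
                        trainLog = "data.frame"))

setValidity("MVModel", function(object) {
  msg <- character()
  if (!object@strategy %in% fusionStrategies())
    msg <- c(msg, sprintf("unknown fusion strategy '%s'", object@strategy))
  if (length(object@viewIds) < 1L || anyDuplicated(object@viewIds))
    msg <- c(msg, "viewIds must be non-empty and distinct")
  if (length(msg)) msg else TRUE
})

#' EvalReport: test-set evaluation of a binary classifier
#'
#' Holds per-case predicted probabilities and labels, the AUC (probability
#' that a random positive outscores a random negative, ties counted 1/2),
#' and the operating point at the threshold maximising Youden's J =
#' sensitivity + specificity - 1.
#'
#' @slot probabilities predicted positive-class probabilities per case.
#' @slot labels true labels (0/1).
#' @slot auc area under the ROC curve, in [0, 1].
#' @slot optimalThreshold Youden-optimal decision threshold (predict
#'   positive when probability >= threshold).
#' @slot sensitivity,specificity achieved at the optimal threshold.
#' @export
setClass("EvalReport",
         representation(probabilities = "numeric", labels = "integer",
                        auc = "numeric", optimalThreshold = "numeric",
                        sensitivity = "numeric", specificity = "numeric"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (length(object@probabilities) != length(object@labels))
    msg <- c(msg, "probabilities and labels differ in length")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Available fusion strategies
#'
#' The four decision-fusion strategies compared by the ablation harness:
#' feature-level fusion by weighted concatenation (the default method) or
#' plain concatenation, and label-level fusion of per-view probabilities by
#' arithmetic or weighted average.
#'
#' @return character vector of strategy names.
#' @export
fusionStrategies <- function() {
  c("weighted_feature", "concat_feature", "label_average", "label_weighted")
}
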