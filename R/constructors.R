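#' Create a ViewVolume
#'
#' @param viewId short view tag, e.g. \code{"sagT1"}.
#' @param voxels 3-D numeric array with dim \code{(depth, height, width)}.
#' @return a \linkS4class{ViewVolume}.
#' @examples
#' v <- viewVolume("axial", array(rnorm(1 * 8 * 8), c(1, 8, 8)))
#' dim(v)
#' @export
viewVolume <- function(viewId, voxels) {
  if (is.null(dim(voxels)))
    stop("voxels has no dim attribute; expected a 3-D array")
  new("ViewVolume", viewId = as.character(viewId), voxels = voxels)
}

#' Create a DatasetSplit
#'
#' @param train,validation,test lists of \linkS4class{MultiViewCase}.
#' @return a \linkS4class{DatasetSplit}.
#' @export
datasetSplit <- function(train, validation, test) {
  new("DatasetSplit", train = train, validation = validation, test = test)
}

#' Configure the shared 3D residual encoder
#'
#' The default is the full-scale configuration whose per-view embedding has
#' 512 dimensions (3D ResNet-10-style: 4 stages of one basic block, channel
#' widths 64/128/256/512). \code{reducedEncoderConfig()} gives the
#' desk-scale variant (8/16/32/64, embedding 64) used for CPU-budget
#' experiments and tests.
#'
#' @param stemChannels channels after the stem convolution.
#' @param blockChannels integer vector of per-stage channel widths.
#' @param blocksPerStage integer vector, basic residual blocks per stage.
#' @param embeddingDim per-view embedding length; must equal
#'   \code{blockChannels[length(blockChannels)]}.
#' @return an \linkS4class{EncoderConfig}.
#' @examples
#' encoderConfig()           # 512-dim embedding default
#' reducedEncoderConfig()    # small CPU test config, 64-dim embedding
#' @export
encoderConfig <- function(stemChannels = 64L,
                          blockChannels = c(64L, 128L, 256L, 512L),
                          blocksPerStage = rep(1L, length(blockChannels)),
                          embeddingDim = blockChannels[length(blockChannels)]) {
  new("EncoderConfig", stemChannels = as.integer(stemChannels),
      blockChannels = as.integer(blockChannels),
      blocksPerStage = as.integer(blocksPerStage),
      embeddingDim = as.integer(embeddingDim))
}

#' @rdname encoderConfig
#' @export
reducedEncoderConfig <- function() {
  encoderConfig(stemChannels = 8L, blockChannels = c(8L, 16L, 32L, 64L))
}

#' Configure training
#'
#' Defaults mirror the reference recipe (Adam, lr 1e-4, 100 epochs, batch
#' 32, beta1 0.9, weight decay 1e-4). Desk-scale phantom experiments use
#' fewer epochs and a larger learning rate; see the package vignette.
#'
#' @param learningRate Adam step size.
#' @param epochs training epochs.
#' @param batchSize cases per mini-batch.
#' @param beta1 Adam first-moment (momentum) coefficient.
#' @param beta2 Adam second-moment coefficient.
#' @param weightDecay L2 coefficient added to parameter gradients.
#' @param posWeight positive-class loss multiplier (1 disables reweighting).
#' @param seed RNG seed governing initialisation and shuffling.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 1e-4, epochs = 100L, batchSize = 32L,
                        beta1 = 0.9, beta2 = 0.999, weightDecay = 1e-4,
                        posWeight = 1, seed = 1L) {
  new("TrainConfig", learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), beta1 = beta1, beta2 = beta2,
      weightDecay = weightDecay, posWeight = posWeight,
      seed = as.integer(seed))
}

#' Specify a synthetic multi-view phantom world
#'
#' Defaults define the standard desk-scale phantom dataset: 100 cases of 4
#' views at 16 x 32 x 32, half positive, lesion amplitude 1.5 over noise sd
#' 0.5, and view windows of width 0.5 offset by 1/nViews: each view renders
#' only half of the lesion's angular extent, the union of views renders all
#' of it. Setting \code{lesionArc} below 1 makes the lesion a focal tear at
#' a random per-case angle, so per-view visibility varies by case — the
#' regime where weighting views can genuinely help.
#'
#' @param nViews views per case.
#' @param shape c(depth, height, width) of every volume.
#' @param nCases total cases generated.
#' @param positiveFraction fraction of lesion-bearing cases, in (0,1).
#' @param signalAmplitude peak lesion intensity (0 = null world).
#' @param noiseSd per-voxel Gaussian noise sd.
#' @param viewInformativeness per-view rendered fraction of the lesion's
#'   angular extent, each in [0,1].
#' @param lesionArc azimuthal fraction the lesion occupies (1 = the full
#'   ellipsoid; < 1 gives a focal tear at a random per-case angle, so
#'   which views can see it varies from case to case).
#' @param seed generation seed; the dataset is a pure function of the spec.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(nViews = 4L, shape = c(16L, 32L, 32L), nCases = 100L,
                        positiveFraction = 0.5, signalAmplitude = 1.5,
                        noiseSd = 0.5,
                        viewInformativeness = rep(0.5, nViews),
                        lesionArc = 1, seed = 1L) {
  new("PhantomSpec", nViews = as.integer(nViews), shape = as.integer(shape),
      nCases = as.integer(nCases), positiveFraction = positiveFraction,
      signalAmplitude = signalAmplitude, noiseSd = noiseSd,
      viewInformativeness = viewInformativeness, lesionArc = lesionArc,
      seed = as.integer(seed))
}
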