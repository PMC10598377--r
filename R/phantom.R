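# Synthetic multi-view phantoms: labelled 3D volumes whose class signal is
# deliberately split across views, so that pooling views is genuinely
# required to see the whole lesion.

# Smooth low-frequency background: 3 random cosine components. Amplitude
# and frequency are kept low (slowly varying bias field, modest relative to
# tissue contrast) so the background does not itself produce lesion-sized,
# lesion-amplitude blobs.
smoothField <- function(shape) {
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  dn <- (seq_len(D) - 1) / D
  hn <- (seq_len(H) - 1) / H
  wn <- (seq_len(W) - 1) / W
  f <- array(0, shape)
  for (k in 1:3) {
    amp <- runif(1, 0.05, 0.15)
    fr <- runif(3, 0.25, 0.75)
    ph <- runif(1, 0, 2 * pi)
    phase <- rep(fr[1] * dn, times = H * W) +
      rep(rep(fr[2] * hn, each = D), times = W) +
      rep(fr[3] * wn, each = D * H)
    f <- f + amp * cos(2 * pi * phase + ph)
  }
  f
}

# Voxel coordinate grids for one shape, as vectors of length D*H*W in
# array (column-major) order.
voxelGrid <- function(shape) {
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  list(d = rep(seq_len(D), times = H * W),
       h = rep(rep(seq_len(H), each = D), times = W),
       w = rep(seq_len(W), each = D * H))
}

#' Generate one phantom case
#'
#' The background of every view is an independent realisation of a smooth
#' low-frequency field plus Gaussian noise. For a positive case an
#' ellipsoidal lesion (smooth profile \code{A * exp(-2 * rho^2)}, truncated
#' at rho = 1.6) with shared centre and radii is added to every view, but
#' view v renders only the voxels whose azimuthal angle around the lesion
#' centre falls in a window of width \code{viewInformativeness[v]},
#' offset by \code{(v-1)/nViews}: each view sees a different part of the
#' lesion, and only the union of views sees all of it. With
#' \code{lesionArc < 1} the lesion occupies only a random azimuthal sector
#' (a focal tear), so on any given case some views render most of it and
#' others none — per-view informativeness then varies case by case.
#'
#' Draws from the current RNG state; seed the RNG (or use
#' \code{\link{generateDataset}}) for reproducibility.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param label 0 (background only) or 1 (lesion planted).
#' @param id case identifier.
#' @return a \linkS4class{MultiViewCase} with raw (unnormalised) volumes.
#' @export
generateCase <- function(spec, label, id = "case") {
  shape <- spec@shape
  radii <- c(runif(1, 0.25, 0.4) * shape[1],
             runif(1, 0.25, 0.4) * shape[2],
             runif(1, 0.25, 0.4) * shape[3])
  lo <- 1 + radii
  hi <- shape - radii
  if (any(lo > hi))
    stop("lesion larger than volume; enlarge shape or shrink radii")
  centre <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
              runif(1, lo[3], hi[3]))
  g <- voxelGrid(shape)
  rho2 <- ((g$d - centre[1]) / radii[1])^2 +
    ((g$h - centre[2]) / radii[2])^2 +
    ((g$w - centre[3]) / radii[3])^2
  profile <- spec@signalAmplitude * exp(-2 * rho2) * (rho2 < 1.6^2)
  azim <- atan2(g$w - centre[3], g$h - centre[2]) / (2 * pi) + 0.5  # [0,1)
  arcStart <- runif(1)
  if (spec@lesionArc < 1)   # focal tear: restrict to a random sector
    profile <- profile * (((azim - arcStart) %% 1) < spec@lesionArc)

  views <- vector("list", spec@nViews)
  for (v in seq_len(spec@nViews)) {
    vol <- smoothField(shape) +
      array(rnorm(prod(shape), sd = spec@noiseSd), shape)
    if (label == 1L && spec@signalAmplitude > 0) {
      off <- (v - 1) / spec@nViews
      inWindow <- ((azim - off) %% 1) < spec@viewInformativeness[v]
      vol <- vol + array(profile * inWindow, shape)
    }
    views[[v]] <- viewVolume(sprintf("view%d", v), vol)
  }
  new("MultiViewCase", caseId = as.character(id), views = views,
      label = as.integer(label))
}

#' Generate a stratified phantom dataset
#'
#' Generates \code{nCases} phantom cases and partitions them 70/10/20 into
#' train/validation/test, stratified by label: each partition receives
#' \code{round(positiveFraction * size)} positives (clamped so both classes
#' are present in every partition). Generation is a pure function of the
#' spec: the same spec (including its seed) always yields the identical
#' dataset.
#'
#' @param spec a \linkS4class{PhantomSpec} with \code{nCases >= 10}.
#' @return a \linkS4class{DatasetSplit} of raw (unnormalised) cases.
#' @export
generateDataset <- function(spec) {
  if (spec@nCases < 10L) stop("need at least 10 cases to form a 70/10/20 split")
  nTrain <- round(0.7 * spec@nCases)
  nVal <- round(0.1 * spec@nCases)
  nTest <- spec@nCases - nTrain - nVal
  # a partition needs >= 2 cases to hold both classes; grow undersized
  # partitions at the expense of the training partition
  grow <- pmax(2L - c(nVal, nTest), 0L)
  nVal <- nVal + grow[1]
  nTest <- nTest + grow[2]
  nTrain <- nTrain - sum(grow)
  sizes <- c(train = nTrain, validation = nVal, test = nTest)
  if (nTrain < 2L)
    stop("too few cases to stratify all three partitions")
  withSeed(spec@seed, {
    parts <- lapply(names(sizes), function(pn) {
      sz <- sizes[[pn]]
      npos <- min(max(round(spec@positiveFraction * sz), 1L), sz - 1L)
      labels <- sample(c(rep(1L, npos), rep(0L, sz - npos)))
      lapply(seq_len(sz), function(i)
        generateCase(spec, labels[i], sprintf("ph_%s_%03d", pn, i)))
    })
    datasetSplit(parts[[1]], parts[[2]], parts[[3]])
  })
}

#' Preprocess every case of a list or split
#'
#' Applies \code{\link{preprocessVolume}} to each view of each case,
#' harmonising all volumes to one shape and z-scoring them.
#'
#' @param cases list of \linkS4class{MultiViewCase}.
#' @param targetDepth,targetHW target shape (depth, in-plane size); default
#'   to the first case's existing shape (z-score only).
#' @return the transformed list of cases.
#' @export
preprocessCases <- function(cases,
                            targetDepth = dim(caseViews(cases[[1]])[[1]])[1],
                            targetHW = dim(caseViews(cases[[1]])[[1]])[2]) {
  lapply(cases, function(cs) {
    new("MultiViewCase", caseId = caseId(cs),
        views = lapply(caseViews(cs), preprocessVolume,
                       targetDepth = targetDepth, targetHW = targetHW),
        label = caseLabel(cs))
  })
}

#' @rdname preprocessCases
#' @param split a \linkS4class{DatasetSplit}.
#' @export
preprocessSplit <- function(split,
                            targetDepth =
                              dim(caseViews(trainCases(split)[[1]])[[1]])[1],
                            targetHW =
                              dim(caseViews(trainCases(split)[[1]])[[1]])[2]) {
  datasetSplit(preprocessCases(trainCases(split), targetDepth, targetHW),
               preprocessCases(valCases(split), targetDepth, targetHW),
               preprocessCases(testCases(split), targetDepth, targetHW))
}
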