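#' Initialise the shared-weight 3D residual encoder
#'
#' Builds the parameter set of the feature-extraction network described by
#' an \linkS4class{EncoderConfig}: a stem (Conv3D 3x3x3 stride 1 + BN3D +
#' ReLU + MaxPool3D 2x2x2), then one sequence of basic residual blocks per
#' stage (conv-BN-ReLU-conv-BN plus identity or 1x1x1 projection shortcut,
#' final ReLU), with stride 2 entering every stage after the first, and a
#' global adaptive average pool producing the per-view embedding. One
#' parameter set encodes every view of every case (shared weights).
#'
#' Convolution weights are He-initialised; batch-norm scale/shift start at
#' 1/0 with running statistics 0/1, so a freshly initialised block with
#' zeroed convolution weights has an identically-zero residual branch in
#' eval mode.
#'
#' @param cfg an \linkS4class{EncoderConfig}.
#' @param seed optional seed for reproducible initialisation; \code{NULL}
#'   uses the current RNG state.
#' @return an encoder parameter list (with the config attached as
#'   \code{$cfg}), suitable for \code{\link{encodeView}} and
#'   \code{\link{trainModel}}.
#' @export
initEncoder <- function(cfg = encoderConfig(), seed = NULL) {
  build <- function() {
    stem <- list(conv = makeConv3d(1L, cfg@stemChannels, 3L, 1L, 1L),
                 bn = makeBatchNorm(cfg@stemChannels))
    stages <- list()
    cin <- cfg@stemChannels
    for (s in seq_along(cfg@blockChannels)) {
      cout <- cfg@blockChannels[s]
      blocks <- list()
      for (b in seq_len(cfg@blocksPerStage[s])) {
        stride <- if (b == 1L && s > 1L) 2L else 1L
        blocks[[b]] <- makeResidualBlock(cin, cout, stride)
        cin <- cout
      }
      names(blocks) <- paste0("block", seq_along(blocks))
      stages[[s]] <- blocks
    }
    if (length(stages))
      names(stages) <- paste0("stage", seq_along(stages))
    list(cfg = cfg, stem = stem, stages = stages)
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' Initialise one basic residual block
#'
#' A basic block computes \code{ReLU(F(x) + shortcut(x))} where the
#' residual branch F is conv3x3x3 (stride as given) - BN - ReLU -
#' conv3x3x3 - BN, and the shortcut is the identity, or a 1x1x1 projection
#' convolution + BN when the channel count or stride changes (so the
#' addition is shape-legal).
#'
#' @param inChannels,outChannels channel counts entering/leaving the block.
#' @param stride spatial stride of the first convolution (1 or 2).
#' @return a block parameter list.
#' @export
makeResidualBlock <- function(inChannels, outChannels, stride = 1L) {
  blk <- list(conv1 = makeConv3d(inChannels, outChannels, 3L, stride, 1L),
              bn1 = makeBatchNorm(outChannels),
              conv2 = makeConv3d(outChannels, outChannels, 3L, 1L, 1L),
              bn2 = makeBatchNorm(outChannels))
  if (inChannels != outChannels || stride != 1L) {
    blk$proj <- makeConv3d(inChannels, outChannels, 1L, stride, 0L)
    blk$bnp <- makeBatchNorm(outChannels)
  }
  blk
}

blockForward <- function(x, blk, training) {
  c1 <- convForward(x, blk$conv1)
  b1 <- bnForward(c1, blk$bn1, training)
  r1 <- reluForward(b1$y)
  c2 <- convForward(r1, blk$conv2)
  b2 <- bnForward(c2, blk$bn2, training)
  if (!is.null(blk$proj)) {
    ps <- convForward(x, blk$proj)
    bp <- bnForward(ps, blk$bnp, training)
    sc <- bp$y
  } else {
    ps <- NULL
    bp <- NULL
    sc <- x
  }
  z <- b2$y + sc
  y <- reluForward(z)
  blk$bn1 <- b1$bn
  blk$bn2 <- b2$bn
  if (!is.null(bp)) blk$bnp <- bp$bn
  list(y = y, blk = blk,
       cache = list(x = x, b1y = b1$y, r1 = r1, z = z,
                    bn1 = b1$cache, bn2 = b2$cache, bnp = bp$cache))
}

blockBackward <- function(dy, blk, cache) {
  dz <- reluBackward(dy, cache$z)
  # residual branch
  bb2 <- bnBackward(dz, blk$bn2, cache$bn2)
  cb2 <- convBackward(cache$r1, blk$conv2, bb2$dx, needDx = TRUE)
  dr1 <- reluBackward(cb2$dx, cache$b1y)
  bb1 <- bnBackward(dr1, blk$bn1, cache$bn1)
  cb1 <- convBackward(cache$x, blk$conv1, bb1$dx, needDx = TRUE)
  dx <- cb1$dx
  grads <- list(conv1 = list(w = cb1$dw),
                bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
                conv2 = list(w = cb2$dw),
                bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta))
  # shortcut
  if (!is.null(blk$proj)) {
    bbp <- bnBackward(dz, blk$bnp, cache$bnp)
    cbp <- convBackward(cache$x, blk$proj, bbp$dx, needDx = TRUE)
    dx <- dx + cbp$dx
    grads$proj <- list(w = cbp$dw)
    grads$bnp <- list(gamma = bbp$dgamma, beta = bbp$dbeta)
  } else {
    dx <- dx + dz
  }
  list(dx = dx, grads = grads)
}

# Forward pass of the whole encoder on a batch (1, D, H, W, N).
# Returns the (embeddingDim x N) embedding matrix, updated parameters
# (running BN statistics) and, when caching, everything backward needs.
encoderForward <- function(x, enc, training = FALSE, keepCache = training) {
  stopifnot(length(dim(x)) == 5L, dim(x)[1] == 1L)
  c1 <- convForward(x, enc$stem$conv)
  b1 <- bnForward(c1, enc$stem$bn, training)
  r1 <- reluForward(b1$y)
  mp <- maxpoolForward(r1, 2L, 2L)
  enc$stem$bn <- b1$bn
  h <- mp$y
  caches <- if (keepCache) list() else NULL
  for (s in seq_along(enc$stages)) {
    for (b in seq_along(enc$stages[[s]])) {
      bf <- blockForward(h, enc$stages[[s]][[b]], training)
      enc$stages[[s]][[b]] <- bf$blk
      if (keepCache) caches[[sprintf("s%db%d", s, b)]] <- bf$cache
      h <- bf$y
    }
  }
  emb <- gapForward(h)
  cache <- if (keepCache) {
    list(x = x, b1y = b1$y, stemBn = b1$cache, mp = mp, preGapDim = dim(h),
         blocks = caches)
  } else NULL
  list(emb = emb, enc = enc, cache = cache)
}

# Backward pass; demb is (embeddingDim x N). Returns encoder gradients
# (input gradients are not needed: the input is data).
encoderBackward <- function(demb, enc, cache) {
  dh <- gapBackward(demb, cache$preGapDim)
  grads <- list(stem = NULL, stages = vector("list", length(enc$stages)))
  names(grads$stages) <- names(enc$stages)
  for (s in rev(seq_along(enc$stages))) {
    grads$stages[[s]] <- vector("list", length(enc$stages[[s]]))
    names(grads$stages[[s]]) <- names(enc$stages[[s]])
    for (b in rev(seq_along(enc$stages[[s]]))) {
      bb <- blockBackward(dh, enc$stages[[s]][[b]],
                          cache$blocks[[sprintf("s%db%d", s, b)]])
      grads$stages[[s]][[b]] <- bb$grads
      dh <- bb$dx
    }
  }
  dr1 <- maxpoolBackward(dh, cache$mp$argmax, dim(cache$b1y))
  db1 <- reluBackward(dr1, cache$b1y)
  bb <- bnBackward(db1, enc$stem$bn, cache$stemBn)
  cb <- convBackward(cache$x, enc$stem$conv, bb$dx, needDx = FALSE)
  grads$stem <- list(conv = list(w = cb$dw),
                     bn = list(gamma = bb$dgamma, beta = bb$dbeta))
  grads
}

#' Apply one residual block to a single feature tensor
#'
#' Evaluates \code{z = F(x) + shortcut(x)} followed by ReLU for one sample,
#' in eval mode (running batch-norm statistics). With all convolution
#' weights of the branch set to zero and freshly initialised batch norms,
#' the output is exactly \code{ReLU(x)}.
#'
#' @param x 4-D numeric array \code{(channels, depth, height, width)}.
#' @param block block parameters from \code{\link{makeResidualBlock}}.
#' @return 4-D array of the block output.
#' @export
residualBlock <- function(x, block) {
  if (!all(is.finite(x))) stop("residualBlock: non-finite input")
  stopifnot(length(dim(x)) == 4L)
  dim(x) <- c(dim(x), 1L)
  out <- blockForward(x, block, training = FALSE)
  y <- out$y
  dim(y) <- dim(y)[1:4]
  y
}

#' Encode one view volume into its embedding
#'
#' Runs a preprocessed \linkS4class{ViewVolume} through the shared encoder
#' in eval mode and returns the per-view feature vector h = f(x) of length
#' \code{embeddingDim} (adaptive average pooling makes the output length
#' independent of the input's spatial size).
#'
#' @param v a \linkS4class{ViewVolume} (preprocessed: z-scored).
#' @param encoder encoder parameters from \code{\link{initEncoder}}.
#' @return numeric embedding vector with attribute \code{viewId}.
#' @export
encodeView <- function(v, encoder) {
  stopifnot(is(v, "ViewVolume"))
  x <- viewData(v)
  dim(x) <- c(1L, dim(x), 1L)
  out <- encoderForward(x, encoder, training = FALSE, keepCache = FALSE)
  emb <- as.numeric(out$emb)
  if (!all(is.finite(emb))) stop("encodeView: non-finite embedding")
  attr(emb, "viewId") <- viewId(v)
  emb
}

#' Count trainable encoder parameters
#'
#' Exact count of trainable parameters (convolution weights and batch-norm
#' scale/shift; running statistics are buffers, not parameters) for a given
#' encoder configuration.
#'
#' @param cfg an \linkS4class{EncoderConfig}.
#' @return integer parameter count.
#' @examples
#' countParameters(reducedEncoderConfig())
#' @export
countParameters <- function(cfg) {
  enc <- withSeed(0L, initEncoder(cfg))
  countTrainable(enc[c("stem", "stages")])
}
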