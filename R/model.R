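#' Create an untrained multi-view model
#'
#' Assembles the shared-weight encoder, the view-scoring network (for the
#' weighted strategies), and the classifier head for a given canonical view
#' order and fusion strategy. For the feature-fusion strategies the head
#' takes the fused n x embeddingDim vector; for the label-fusion strategies
#' a shared single-view head (embeddingDim -> hidden -> 1) is applied to
#' every view and the per-view probabilities are combined.
#'
#' @param viewIds canonical view order (character vector, distinct).
#' @param encoderConfig an \linkS4class{EncoderConfig}.
#' @param strategy one of \code{fusionStrategies()}.
#' @param headHidden classifier hidden width; defaults to the embedding
#'   dimension (512 in the full-scale configuration).
#' @param seed initialisation seed.
#' @return an \linkS4class{MVModel}.
#' @export
mvModel <- function(viewIds, encoderConfig = mvfusion::encoderConfig(),
                    strategy = "weighted_feature",
                    headHidden = encoderConfig@embeddingDim, seed = 1L) {
  strategy <- match.arg(strategy, fusionStrategies())
  n <- length(viewIds)
  d <- encoderConfig@embeddingDim
  params <- withSeed(seed, {
    # initialisation order is fixed and strategy-independent, so models
    # that differ only in fusion strategy start from identical weights
    p <- list(encoder = initEncoder(encoderConfig),
              weightNet = initWeightNet(d, 64L))
    headIn <- if (strategy %in% c("weighted_feature", "concat_feature"))
      n * d else d
    p$head <- initHead(headIn, as.integer(headHidden))
    p
  })
  new("MVModel", encoderConfig = encoderConfig, viewIds = viewIds,
      strategy = strategy, params = params,
      trainLog = data.frame(epoch = integer(), train_loss = numeric(),
                            val_auc = numeric()))
}

# Stack the views of `cases` into one encoder batch (1, D, H, W, n*B);
# volume order is view-fastest: index (b-1)*n + v. Verifies every case has
# the model's views in canonical order (reordering by id if needed).
stackCases <- function(cases, viewIds) {
  n <- length(viewIds)
  B <- length(cases)
  d0 <- dim(caseViews(cases[[1]])[[1]])
  x <- array(0, c(1L, d0, n * B))
  for (b in seq_len(B)) {
    vs <- caseViews(cases[[b]])
    ids <- vapply(vs, viewId, character(1))
    ord <- match(viewIds, ids)
    if (anyNA(ord))
      stop(sprintf("case '%s' lacks view(s): %s", caseId(cases[[b]]),
                   paste(viewIds[is.na(ord)], collapse = ", ")))
    for (v in seq_len(n)) {
      vol <- viewData(vs[[ord[v]]])
      if (!identical(dim(vol), d0))
        stop(sprintf("case '%s' view '%s' has shape %s, expected %s",
                     caseId(cases[[b]]), viewIds[v],
                     paste(dim(vol), collapse = "x"),
                     paste(d0, collapse = "x")))
      x[1, , , , (b - 1L) * n + v] <- vol
    }
  }
  x
}

# Forward pass on a batch of cases. Returns probabilities, mean loss,
# updated params (BN running stats) and the cache for the backward pass.
modelForward <- function(params, strategy, x, n, B, y = NULL,
                         training = FALSE, posWeight = 1) {
  ef <- encoderForward(x, params$encoder, training = training,
                       keepCache = training)
  params$encoder <- ef$enc
  E <- ef$emb                                # d x (n*B)
  d <- nrow(E)
  cache <- list(encoder = ef$cache, E = E, n = n, B = B)

  if (strategy == "weighted_feature") {
    wf <- weightNetForward(E, params$weightNet, n, B)
    U <- array(E, c(d, n, B)) *
      rep(wf$A, each = d)                    # scale block v of case b by A[v,b]
    dim(U) <- c(d * n, B)
    hf <- headForward(U, params$head)
    p <- hf$p
    cache <- c(cache, list(wf = wf, hf = hf, U = U))
  } else if (strategy == "concat_feature") {
    U <- E
    dim(U) <- c(d * n, B)
    hf <- headForward(U, params$head)
    p <- hf$p
    cache <- c(cache, list(hf = hf, U = U))
  } else if (strategy == "label_average") {
    hf <- headForward(E, params$head)        # batch of n*B single views
    P <- matrix(hf$p, nrow = n)
    p <- colMeans(P)
    cache <- c(cache, list(hf = hf, P = P))
  } else {                                   # label_weighted
    wf <- weightNetForward(E, params$weightNet, n, B)
    hf <- headForward(E, params$head)
    P <- matrix(hf$p, nrow = n)
    p <- colSums(wf$A * P)
    cache <- c(cache, list(wf = wf, hf = hf, P = P))
  }

  loss <- if (is.null(y)) NA_real_ else {
    pc <- clampProb(p)
    mean(-(posWeight * y * log(pc) + (1 - y) * log(1 - pc)))
  }
  list(p = p, loss = loss, params = params, cache = cache)
}

# Backward pass for the mean cross-entropy loss over the batch.
modelBackward <- function(params, strategy, cache, y, posWeight = 1) {
  n <- cache$n
  B <- cache$B
  E <- cache$E
  d <- nrow(E)
  grads <- list()

  if (strategy %in% c("weighted_feature", "concat_feature")) {
    p <- cache$hf$p
    # d(mean loss)/d(logit) for sigmoid + cross-entropy
    dlogit <- ((1 - y) * p - posWeight * y * (1 - p)) / B
    hb <- headBackward(dlogit, params$head, cache$hf$cache)
    grads$head <- hb$grads
    dU <- hb$dU
    if (strategy == "weighted_feature") {
      A <- cache$wf$A
      dU3 <- array(dU, c(d, n, B))
      E3 <- array(E, c(d, n, B))
      dE <- dU3 * rep(A, each = d)
      dA <- apply(dU3 * E3, c(2, 3), sum)
      dim(dE) <- c(d, n * B)
      wb <- weightNetBackward(dA, A, params$weightNet, cache$wf$cache)
      grads$weightNet <- wb$grads
      dE <- dE + wb$dE
    } else {
      dE <- dU
      dim(dE) <- c(d, n * B)
    }
  } else {
    P <- cache$P
    pFused <- clampProb(if (strategy == "label_average") colMeans(P)
                        else colSums(cache$wf$A * P))
    dpFused <- ((1 - y) / (1 - pFused) - posWeight * y / pFused) / B
    if (strategy == "label_average") {
      dP <- matrix(rep(dpFused / n, each = n), nrow = n)
    } else {
      A <- cache$wf$A
      dP <- A * rep(dpFused, each = n)
      dA <- P * rep(dpFused, each = n)
      wb <- weightNetBackward(dA, A, params$weightNet, cache$wf$cache)
      grads$weightNet <- wb$grads
    }
    dlogit <- as.numeric(dP) * cache$hf$p * (1 - cache$hf$p)
    hb <- headBackward(dlogit, params$head, cache$hf$cache)
    grads$head <- hb$grads
    dE <- hb$dU
    if (strategy == "label_weighted") dE <- dE + wb$dE
  }

  grads$encoder <- encoderBackward(dE, params$encoder, cache$encoder)
  grads
}

#' Predict positive-class probabilities for cases
#'
#' Runs the model in eval mode (running batch-norm statistics; fully
#' deterministic) over the cases in mini-batches.
#'
#' @param model a trained \linkS4class{MVModel}.
#' @param cases list of preprocessed \linkS4class{MultiViewCase}.
#' @param batchSize cases per forward batch.
#' @return numeric vector of probabilities, one per case.
#' @export
predictProbs <- function(model, cases, batchSize = 32L) {
  n <- nViews(model)
  out <- numeric(length(cases))
  idx <- split(seq_along(cases), ceiling(seq_along(cases) / batchSize))
  for (ii in idx) {
    x <- stackCases(cases[ii], model@viewIds)
    fw <- modelForward(model@params, model@strategy, x, n, length(ii),
                       training = FALSE)
    out[ii] <- fw$p
  }
  out
}
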