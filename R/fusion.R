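# Fusion of per-view embeddings or per-view predictions into one decision.

# Accept embeddings as a list of equal-length numeric vectors or as a
# (dim x n) matrix; return the matrix form.
asEmbeddingMatrix <- function(embeddings) {
  if (is.matrix(embeddings)) return(embeddings)
  if (!is.list(embeddings) || !length(embeddings))
    stop("embeddings must be a non-empty list of numeric vectors or a matrix")
  lens <- lengths(embeddings)
  if (length(unique(lens)) != 1L)
    stop(sprintf("embeddings differ in length: %s",
                 paste(lens, collapse = ", ")))
  matrix(unlist(embeddings, use.names = FALSE), nrow = lens[1])
}

#' Initialise the view-scoring network
#'
#' One shared two-layer perceptron (embeddingDim -> hidden -> 1) applied to
#' each view's embedding independently; the resulting per-view scalar
#' logits are softmax-normalised across views to give the fusion weights.
#' Sharing the scoring parameters across views keeps the mechanism valid
#' for any number of views, consistent with the shared encoder.
#'
#' The scoring MLP's output layer is zero-initialised, so training starts
#' from exactly uniform view weights (weighted concatenation = plain
#' concatenation at step 0) and departs from uniformity only as evidence
#' for view-specific informativeness accumulates; a randomly initialised
#' gate would inject per-case weight noise into the head and encoder during
#' the earliest, most sensitive steps.
#'
#' @param embeddingDim length of each view embedding.
#' @param hidden hidden width of the scoring MLP.
#' @return weight-net parameter list.
#' @export
initWeightNet <- function(embeddingDim, hidden = 64L) {
  list(fc1 = makeLinear(embeddingDim, hidden),
       fc2 = list(W = matrix(0, 1L, hidden), b = 0))
}

# Forward on an (dim x n*B) embedding matrix; returns softmax weights
# (n x B) and the cache used by the backward pass.
weightNetForward <- function(E, wn, n, B) {
  a1 <- linearForward(E, wn$fc1)
  z1 <- reluForward(a1)
  s <- linearForward(z1, wn$fc2)          # 1 x (n*B)
  logits <- matrix(s, nrow = n)
  A <- softmaxCols(logits)
  list(A = A, cache = list(E = E, a1 = a1, z1 = z1, n = n, B = B))
}

# dA is (n x B); returns dE (dim x n*B) plus weight-net gradients.
weightNetBackward <- function(dA, A, wn, cache) {
  dS <- A * (dA - rep(colSums(A * dA), each = nrow(A)))
  ds <- matrix(dS, nrow = 1)
  l2 <- linearBackward(cache$z1, wn$fc2, ds)
  da1 <- reluBackward(l2$dx, cache$a1)
  l1 <- linearBackward(cache$E, wn$fc1, da1)
  list(dE = l1$dx,
       grads = list(fc1 = list(W = l1$dW, b = l1$db),
                    fc2 = list(W = l2$dW, b = l2$db)))
}

#' Compute softmax-normalised view weights
#'
#' Each view's embedding is scored by the shared weight net; the scalar
#' logits are softmax-normalised across views, so the weights are
#' nonnegative and sum to one. With a single view the weight is exactly 1.
#'
#' @param embeddings list of equal-length numeric vectors (one per view) or
#'   an (embeddingDim x n) matrix.
#' @param weightNet parameters from \code{\link{initWeightNet}}.
#' @return numeric weight vector of length n on the probability simplex.
#' @export
computeViewWeights <- function(embeddings, weightNet) {
  E <- asEmbeddingMatrix(embeddings)
  if (nrow(E) != ncol(weightNet$fc1$W))
    stop(sprintf("embedding length %d does not match weight net input %d",
                 nrow(E), ncol(weightNet$fc1$W)))
  out <- weightNetForward(E, weightNet, n = ncol(E), B = 1L)
  as.numeric(out$A)
}

#' Weighted feature fusion
#'
#' Scales each view's embedding by its scalar weight and concatenates the
#' scaled embeddings in canonical view order, giving the unified visual
#' feature of length n x embeddingDim.
#'
#' @param embeddings list of per-view embeddings or (dim x n) matrix.
#' @param weights numeric vector of length n (typically softmax weights
#'   from \code{\link{computeViewWeights}}).
#' @return fused numeric vector of length \code{n * embeddingDim}.
#' @export
fuseWeighted <- function(embeddings, weights) {
  E <- asEmbeddingMatrix(embeddings)
  if (length(weights) != ncol(E))
    stop(sprintf("%d weights for %d views", length(weights), ncol(E)))
  if (any(weights < 0)) stop("view weights must be nonnegative")
  as.numeric(E * rep(weights, each = nrow(E)))
}

#' Plain concatenation fusion
#'
#' The unweighted feature-fusion baseline: concatenates the embeddings in
#' canonical view order (equivalently, \code{\link{fuseWeighted}} with all
#' weights fixed at 1).
#'
#' @param embeddings list of per-view embeddings or (dim x n) matrix.
#' @return fused numeric vector of length \code{n * embeddingDim}.
#' @export
fuseConcat <- function(embeddings) {
  E <- asEmbeddingMatrix(embeddings)
  as.numeric(E)
}

#' Initialise the two-layer classifier head
#'
#' The first layer maps the fused feature (length n x embeddingDim) to
#' width \code{hidden} (512 in the full-scale configuration); after a ReLU
#' the second layer outputs one logit which a sigmoid squashes to the
#' positive-class probability.
#'
#' @param inDim fused feature length the head expects.
#' @param hidden hidden width (the embedding dimension by default
#'   convention).
#' @return head parameter list.
#' @export
initHead <- function(inDim, hidden = 512L) {
  list(fc1 = makeLinear(inDim, hidden),
       fc2 = makeLinear(hidden, 1L, sd = sqrt(1 / hidden)))
}

headForward <- function(U, head) {
  a1 <- linearForward(U, head$fc1)
  z1 <- reluForward(a1)
  logit <- linearForward(z1, head$fc2)
  list(p = as.numeric(sigmoid(logit)), logit = as.numeric(logit),
       cache = list(U = U, a1 = a1, z1 = z1))
}

# dlogit is a length-B vector; returns dU and head gradients.
headBackward <- function(dlogit, head, cache) {
  dl <- matrix(dlogit, nrow = 1)
  l2 <- linearBackward(cache$z1, head$fc2, dl)
  da1 <- reluBackward(l2$dx, cache$a1)
  l1 <- linearBackward(cache$U, head$fc1, da1)
  list(dU = l1$dx,
       grads = list(fc1 = list(W = l1$dW, b = l1$db),
                    fc2 = list(W = l2$dW, b = l2$db)))
}

#' Classify a fused feature vector
#'
#' Applies the two-layer head to one fused feature and returns the
#' predicted positive-class probability.
#'
#' @param fused fused feature vector (length must match the head).
#' @param head parameters from \code{\link{initHead}}.
#' @return probability in [0, 1].
#' @export
classify <- function(fused, head) {
  if (length(fused) != ncol(head$fc1$W))
    stop(sprintf("fused length %d does not match head input %d",
                 length(fused), ncol(head$fc1$W)))
  headForward(matrix(fused, ncol = 1), head)$p
}

#' Label fusion by class averaging
#'
#' @param predictions numeric vector of per-view positive-class
#'   probabilities.
#' @return their arithmetic mean.
#' @export
fuseLabelAverage <- function(predictions) {
  if (!length(predictions)) stop("no per-view predictions to fuse")
  mean(predictions)
}

#' Label fusion by class-probability weighting
#'
#' @param predictions numeric vector of per-view probabilities.
#' @param weights simplex weights of matching length.
#' @return the weighted average \code{sum(weights * predictions)}.
#' @export
fuseLabelWeighted <- function(predictions, weights) {
  if (length(predictions) != length(weights))
    stop(sprintf("%d predictions but %d weights", length(predictions),
                 length(weights)))
  sum(weights * predictions)
}

#' Binary cross-entropy loss
#'
#' \code{L(y, yhat) = -(y log(yhat) + (1 - y) log(1 - yhat))} with natural
#' logarithms; predictions are clamped to [1e-7, 1 - 1e-7] so the loss is
#' finite on the closed interval.
#'
#' @param y true label(s), each 0 or 1.
#' @param yhat predicted probability(ies) in [0, 1]; recycled against y.
#' @return nonnegative loss value(s).
#' @examples
#' crossEntropy(1, 0.5)   # log(2)
#' @export
crossEntropy <- function(y, yhat) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- clampProb(yhat)
  -(y * log(p) + (1 - y) * log(1 - p))
}
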