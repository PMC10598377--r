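# Layer primitives for the 3D network. All feature tensors are numeric
# arrays with dim c(C, D, H, W, N): channel fastest, sample slowest, so a
# matrix(x, nrow = C) view exposes per-channel rows. Backward passes are
# hand-derived and verified against finite differences in the test suite.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
TRAINABLE_LEAVES <- c("w", "gamma", "beta", "W", "b")

# ---- parameter constructors -------------------------------------------------

makeConv3d <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  fanin <- cin * k^3
  list(w = matrix(rnorm(fanin * cout, sd = sqrt(2 / fanin)), fanin, cout),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       cin = as.integer(cin), cout = as.integer(cout))
}

makeBatchNorm <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c), rm = rep(0, c), rv = rep(1, c))
}

makeLinear <- function(nin, nout, sd = sqrt(2 / nin)) {
  list(W = matrix(rnorm(nin * nout, sd = sd), nout, nin), b = rep(0, nout))
}

# ---- conv3d -----------------------------------------------------------------

convForward <- function(x, cv) {
  .cpp_conv3d_fwd(x, dim(x), cv$w, cv$k, cv$k, cv$k, cv$stride, cv$pad)
}

convBackward <- function(x, cv, dy, needDx = TRUE) {
  .cpp_conv3d_bwd(x, dim(x), cv$w, dy, cv$k, cv$k, cv$k, cv$stride, cv$pad,
                  needDx)
}

# ---- batch norm -------------------------------------------------------------

# In training mode normalises with batch statistics (biased variance) and
# updates running statistics (unbiased variance, momentum BN_MOMENTUM); in
# eval mode uses the stored running statistics.
bnForward <- function(x, bn, training) {
  d <- dim(x)
  C <- d[1]
  xm <- matrix(x, nrow = C)
  if (training) {
    m <- ncol(xm)
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * invstd
    y <- xhat * bn$gamma + bn$beta
    dim(y) <- d
    unb <- if (m > 1) m / (m - 1) else 1
    bn$rm <- (1 - BN_MOMENTUM) * bn$rm + BN_MOMENTUM * mu
    bn$rv <- (1 - BN_MOMENTUM) * bn$rv + BN_MOMENTUM * v * unb
    list(y = y, bn = bn, cache = list(xhat = xhat, invstd = invstd, m = m))
  } else {
    y <- (xm - bn$rm) / sqrt(bn$rv + BN_EPS) * bn$gamma + bn$beta
    dim(y) <- d
    list(y = y, bn = bn, cache = NULL)
  }
}

bnBackward <- function(dy, bn, cache) {
  d <- dim(dy)
  C <- d[1]
  dym <- matrix(dy, nrow = C)
  xhat <- cache$xhat
  m <- cache$m
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * bn$gamma
  dx <- (cache$invstd / m) *
    (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Eval-mode batch norm backward (affine with fixed statistics); only needed
# for gradient checks, training always uses batch statistics.
bnBackwardEval <- function(dy, bn) {
  d <- dim(dy)
  dym <- matrix(dy, nrow = d[1])
  dx <- dym * (bn$gamma / sqrt(bn$rv + BN_EPS))
  dim(dx) <- d
  dx
}

# ---- relu / pooling ---------------------------------------------------------

reluForward <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

reluBackward <- function(dy, x) {
  dy * (x > 0)
}

maxpoolForward <- function(x, k = 2L, stride = 2L) {
  .cpp_maxpool3d_fwd(x, dim(x), k, stride)
}

maxpoolBackward <- function(dy, argmax, xdim) {
  dx <- .cpp_maxpool3d_bwd(dy, argmax, prod(xdim))
  dim(dx) <- xdim
  dx
}

# Global (adaptive) average pool to a single spatial cell: (C,D,H,W,N) ->
# embedding matrix (C, N).
gapForward <- function(x) {
  d <- dim(x)
  C <- d[1]; N <- d[5]; S <- prod(d[2:4])
  dim(x) <- c(C * S, N)
  e <- matrix(0, C, N)
  for (n in seq_len(N)) e[, n] <- rowMeans(matrix(x[, n], nrow = C))
  e
}

gapBackward <- function(de, xdim) {
  S <- prod(xdim[2:4])
  dx <- array(0, xdim)
  dxm <- matrix(dx, nrow = xdim[1] * S)
  for (n in seq_len(xdim[5]))
    dxm[, n] <- rep(de[, n] / S, times = S)
  dim(dxm) <- xdim
  dxm
}

# ---- linear -----------------------------------------------------------------

linearForward <- function(x, ln) {
  ln$W %*% x + ln$b
}

linearBackward <- function(x, ln, dy) {
  list(dx = crossprod(ln$W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))
}

# ---- recursive parameter utilities -----------------------------------------

# Walk a nested parameter list and apply f to every trainable leaf,
# mirroring the structure. `other` is a parallel structure (grads or
# optimiser state) whose matching leaves are passed as f's second argument.
mapTrainable <- function(params, f, other = NULL) {
  if (!is.list(params)) return(params)
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p)) {
      params[[nm]] <- mapTrainable(p, f, other[[nm]])
    } else if (nm %in% TRAINABLE_LEAVES && is.numeric(p)) {
      params[[nm]] <- f(p, other[[nm]])
    }
  }
  params
}

zeroLike <- function(params) {
  mapTrainable(params, function(p, o) { p[] <- 0; p })
}

countTrainable <- function(params) {
  total <- 0
  mapTrainable(params, function(p, o) { total <<- total + length(p); p })
  total
}

# ---- Adam -------------------------------------------------------------------

adamInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

# One Adam step with L2 weight decay folded into the gradient (classic
# Adam-with-L2; decay applies to every trainable leaf).
adamStep <- function(params, grads, state, lr, beta1, beta2, weightDecay,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  step <- function(path) {
    p <- getLeaf(params, path); g <- getLeaf(grads, path)
    if (is.null(g)) return()
    g <- g + weightDecay * p
    m <- beta1 * getLeaf(state$m, path) + (1 - beta1) * g
    v <- beta2 * getLeaf(state$v, path) + (1 - beta2) * g * g
    state$m <<- setLeaf(state$m, path, m)
    state$v <<- setLeaf(state$v, path, v)
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    params <<- setLeaf(params, path, p)
  }
  walk <- function(node, path) {
    for (nm in names(node)) {
      child <- node[[nm]]
      if (is.list(child)) walk(child, c(path, nm))
      else if (nm %in% TRAINABLE_LEAVES && is.numeric(child))
        step(c(path, nm))
    }
  }
  walk(params, character())
  list(params = params, state = state)
}

getLeaf <- function(x, path) {
  for (nm in path) {
    x <- x[[nm]]
    if (is.null(x)) return(NULL)
  }
  x
}

setLeaf <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
  } else {
    x[[path[1]]] <- setLeaf(x[[path[1]]], path[-1], value)
  }
  x
}
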