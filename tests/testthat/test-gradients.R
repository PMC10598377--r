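# Hand-derived backward passes checked against central finite differences,
# and the conv kernel against a straight-line R convolution.

mv <- asNamespace("mvfusion")

naiveConv3d <- function(x, w5, stride, pad) {
  d <- dim(x); k <- dim(w5)
  Do <- (d[2] + 2 * pad - k[2]) %/% stride + 1
  Ho <- (d[3] + 2 * pad - k[3]) %/% stride + 1
  Wo <- (d[4] + 2 * pad - k[4]) %/% stride + 1
  y <- array(0, c(k[5], Do, Ho, Wo, d[5]))
  for (n in seq_len(d[5])) for (co in seq_len(k[5]))
    for (od in seq_len(Do)) for (oh in seq_len(Ho)) for (ow in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(k[1])) for (a in seq_len(k[2]))
        for (b in seq_len(k[3])) for (cc in seq_len(k[4])) {
          di <- (od - 1) * stride - pad + a
          hi <- (oh - 1) * stride - pad + b
          wi <- (ow - 1) * stride - pad + cc
          if (di >= 1 && di <= d[2] && hi >= 1 && hi <= d[3] &&
              wi >= 1 && wi <= d[4])
            acc <- acc + x[ci, di, hi, wi, n] * w5[ci, a, b, cc, co]
        }
      y[co, od, oh, ow, n] <- acc
    }
  y
}

test_that("conv3d forward equals a straight-line convolution (stride 1 and 2)", {
  set.seed(30)
  x <- array(rnorm(2 * 4 * 5 * 6 * 2), c(2, 4, 5, 6, 2))
  w5 <- array(rnorm(2 * 27 * 3), c(2, 3, 3, 3, 3))
  for (stride in 1:2) {
    cv <- list(w = matrix(w5, ncol = 3), k = 3L, stride = as.integer(stride),
               pad = 1L)
    expect_equal(mv$convForward(x, cv), naiveConv3d(x, w5, stride, 1),
                 tolerance = 1e-12)
  }
})

test_that("full-model gradients match finite differences for every strategy", {
  set.seed(31)
  cfgE <- encoderConfig(stemChannels = 2L, blockChannels = c(2L, 3L),
                        blocksPerStage = c(1L, 1L), embeddingDim = 3L)
  n <- 2L; B <- 3L
  x <- array(rnorm(1 * 6 * 8 * 8 * (n * B)), c(1, 6, 8, 8, n * B))
  y <- c(1, 0, 1)
  leaves <- list(c("encoder", "stem", "conv", "w"),
                 c("encoder", "stages", "stage1", "block1", "conv1", "w"),
                 c("encoder", "stages", "stage2", "block1", "conv2", "w"),
                 c("encoder", "stages", "stage2", "block1", "proj", "w"),
                 c("encoder", "stages", "stage2", "block1", "bn2", "gamma"),
                 c("head", "fc1", "W"), c("head", "fc2", "b"),
                 c("weightNet", "fc1", "W"), c("weightNet", "fc2", "b"))
  eps <- 1e-5
  for (strat in fusionStrategies()) {
    model <- mvModel(c("a", "b"), cfgE, strat, headHidden = 4L,
                     seed = 7L + match(strat, fusionStrategies()))
    params <- model@params
    fw <- mv$modelForward(params, strat, x, n, B, y, training = TRUE)
    gr <- mv$modelBackward(params, strat, fw$cache, y)
    lossAt <- function(p)
      mv$modelForward(p, strat, x, n, B, y, training = TRUE)$loss
    for (path in leaves) {
      g <- mv$getLeaf(gr, path)
      if (is.null(g)) next   # strategy without a weight net
      p0 <- mv$getLeaf(params, path)
      idx <- sample(length(p0), min(3L, length(p0)))
      for (i in idx) {
        pp <- p0; pp[i] <- pp[i] + eps
        pm <- p0; pm[i] <- pm[i] - eps
        num <- (lossAt(mv$setLeaf(params, path, pp)) -
                  lossAt(mv$setLeaf(params, path, pm))) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(1e-4, abs(num) + abs(g[i])), 1e-4)
      }
    }
  }
})

test_that("maxpool and batch-norm backward match finite differences", {
  set.seed(32)
  x <- array(rnorm(2 * 4 * 4 * 4 * 2), c(2, 4, 4, 4, 2))
  # scalar objective: weighted sum of outputs
  wy <- NULL
  fmax <- function(x) {
    out <- mv$maxpoolForward(x, 2L, 2L)
    if (is.null(wy)) wy <<- rnorm(length(out$y))
    sum(out$y * wy)
  }
  out <- mv$maxpoolForward(x, 2L, 2L)
  f0 <- fmax(x)
  dy <- array(wy, dim(out$y))
  dx <- mv$maxpoolBackward(dy, out$argmax, dim(x))
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + 1e-6
    expect_equal((fmax(xp) - f0) / 1e-6, dx[i], tolerance = 1e-3)
  }

  bn <- mv$makeBatchNorm(2L)
  bn$gamma <- runif(2, 0.5, 1.5); bn$beta <- rnorm(2)
  wb <- rnorm(length(x))
  fbn <- function(x) sum(mv$bnForward(x, bn, TRUE)$y * wb)
  fw <- mv$bnForward(x, bn, TRUE)
  bb <- mv$bnBackward(array(wb, dim(x)), bn, fw$cache)
  f0 <- fbn(x)
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + 1e-6
    expect_equal((fbn(xp) - f0) / 1e-6, bb$dx[i], tolerance = 1e-3)
  }
})
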