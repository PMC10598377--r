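# Shared-weight 3D residual encoder.

test_that("residual block with zeroed branch weights reproduces ReLU(x)", {
  set.seed(20)
  blk <- makeResidualBlock(3L, 3L, 1L)
  blk$conv1$w[] <- 0
  blk$conv2$w[] <- 0
  x <- array(rnorm(3 * 4 * 6 * 6), c(3, 4, 6, 6))
  expect_equal(residualBlock(x, blk), array(pmax(x, 0), dim(x)),
               tolerance = 0)

  # all-zero input stays all-zero for any branch weights (fresh BN stats)
  x0 <- array(0, c(3, 4, 6, 6))
  expect_true(all(residualBlock(x0, makeResidualBlock(3L, 3L, 1L)) == 0))

  expect_error(residualBlock(array(NaN, c(3, 4, 6, 6)), blk), "non-finite")
})

test_that("single-voxel residual block matches hand-computed arithmetic", {
  # 1 channel, 1x1x1 input, 1x1x1 projection-free block with hand-set
  # weights; eval-mode BN with fresh stats is (x * gamma / sqrt(1 + eps)).
  blk <- makeResidualBlock(1L, 1L, 1L)
  # zero out all taps except the kernel centre (offset (2,2,2) of 3^3)
  centre <- 1 + 1 * 1 + 3 * 1 + 9 * 1   # cin=1 ordering: 1 + (1 + 3*(1 + 3*1))
  blk$conv1$w[] <- 0; blk$conv1$w[14, 1] <- 0.5
  blk$conv2$w[] <- 0; blk$conv2$w[14, 1] <- -2
  x <- array(3, c(1, 1, 1, 1))
  bnEval <- function(v) v / sqrt(1 + 1e-5)
  f <- bnEval(-2 * max(bnEval(0.5 * 3), 0))   # conv-BN-ReLU-conv-BN
  expect_equal(as.numeric(residualBlock(x, blk)),
               max(f + 3, 0), tolerance = 1e-12)
})

test_that("embeddings have the configured length and views share weights", {
  set.seed(21)
  enc <- initEncoder(tinyEncoderConfig())
  v1 <- viewVolume("a", array(rnorm(8 * 12 * 12), c(8, 12, 12)))
  v2 <- viewVolume("b", array(rnorm(8 * 12 * 12), c(8, 12, 12)))
  e1 <- encodeView(v1, enc)
  e2 <- encodeView(v2, enc)
  expect_length(e1, 4L)
  expect_identical(attr(e1, "viewId"), "a")

  # embedding length is invariant to input depth (adaptive pooling)
  v3 <- viewVolume("c", array(rnorm(12 * 12 * 12), c(12, 12, 12)))
  expect_length(encodeView(v3, enc), 4L)

  # eval-mode determinism: bitwise-equal repeat
  expect_identical(encodeView(v1, enc), encodeView(v1, enc))

  # shared weights: mutating the single parameter set changes both views'
  # embeddings identically (same delta pathway)
  enc2 <- enc
  enc2$stem$conv$w <- enc2$stem$conv$w * 1.5
  d1 <- encodeView(v1, enc2) - e1
  d2 <- encodeView(v2, enc2) - e2
  expect_false(isTRUE(all.equal(d1, e1 * 0)))
  expect_false(isTRUE(all.equal(d2, e2 * 0)))
})

test_that("default configuration emits 512-dimensional embeddings", {
  set.seed(22)
  enc <- initEncoder(encoderConfig())
  v <- viewVolume("sagT1", array(rnorm(8 * 16 * 16), c(8, 16, 16)))
  expect_length(encodeView(v, enc), 512L)
})

test_that("countParameters matches independent per-layer arithmetic", {
  # independent oracle: sum closed-form layer counts (convs have no bias;
  # BN contributes 2 per channel)
  oracleCount <- function(stem, channels) {
    conv <- function(cin, cout, k) cin * k^3 * cout
    total <- conv(1, stem, 3) + 2 * stem
    cin <- stem
    for (s in seq_along(channels)) {
      cout <- channels[s]
      stride <- if (s > 1) 2 else 1
      total <- total + conv(cin, cout, 3) + 2 * cout +
        conv(cout, cout, 3) + 2 * cout
      if (cin != cout || stride != 1)
        total <- total + conv(cin, cout, 1) + 2 * cout
      cin <- cout
    }
    total
  }
  expect_identical(countParameters(reducedEncoderConfig()),
                   oracleCount(8, c(8, 16, 32, 64)))
  expect_identical(countParameters(encoderConfig()),
                   oracleCount(64, c(64, 128, 256, 512)))

  # zero stages: stem only
  cfg0 <- encoderConfig(stemChannels = 4L, blockChannels = integer(0),
                        blocksPerStage = integer(0), embeddingDim = 4L)
  expect_identical(countParameters(cfg0), 1 * 27 * 4 + 2 * 4)

  # doubling depth strictly increases the count
  cfg1 <- encoderConfig(stemChannels = 4L, blockChannels = c(4L, 8L),
                        blocksPerStage = c(1L, 1L), embeddingDim = 8L)
  cfg2 <- encoderConfig(stemChannels = 4L, blockChannels = c(4L, 8L),
                        blocksPerStage = c(2L, 2L), embeddingDim = 8L)
  expect_gt(countParameters(cfg2), countParameters(cfg1))
})

test_that("encoder config validity catches inconsistent architectures", {
  expect_error(encoderConfig(blockChannels = c(8L, 16L),
                             blocksPerStage = c(1L, 1L, 1L)), "equal length")
  expect_error(encoderConfig(blockChannels = c(8L, 16L), embeddingDim = 32L),
               "embeddingDim")
})
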