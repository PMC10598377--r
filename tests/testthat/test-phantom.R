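# Synthetic multi-view phantom generator.

test_that("generation is a pure function of the spec", {
  spec <- tinyPhantomSpec(seed = 7L)
  a <- generateDataset(spec)
  b <- generateDataset(spec)
  expect_identical(labelsOf(trainCases(a)), labelsOf(trainCases(b)))
  expect_identical(viewData(caseViews(trainCases(a)[[3]])[[2]]),
                   viewData(caseViews(trainCases(b)[[3]])[[2]]))
  expect_identical(viewData(caseViews(testCases(a)[[1]])[[1]]),
                   viewData(caseViews(testCases(b)[[1]])[[1]]))
})

test_that("the 70/10/20 split is stratified with round(fraction * size) positives", {
  split <- generateDataset(phantomSpec(nCases = 100L, shape = c(8L, 8L, 8L),
                                       seed = 1L))
  expect_length(trainCases(split), 70L)
  expect_length(valCases(split), 10L)
  expect_length(testCases(split), 20L)
  expect_identical(sum(labelsOf(trainCases(split))), 35L)
  expect_identical(sum(labelsOf(valCases(split))), 5L)
  expect_identical(sum(labelsOf(testCases(split))), 10L)
  # no case id in two partitions (validity enforces this; spot-check)
  ids <- c(vapply(trainCases(split), caseId, ""),
           vapply(valCases(split), caseId, ""),
           vapply(testCases(split), caseId, ""))
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("minimal datasets still contain both classes in every partition", {
  split <- generateDataset(phantomSpec(nCases = 10L, shape = c(8L, 8L, 8L),
                                       nViews = 2L,
                                       viewInformativeness = c(0.5, 0.5),
                                       seed = 2L))
  for (part in list(trainCases(split), valCases(split), testCases(split))) {
    expect_gte(sum(labelsOf(part)), 1L)
    expect_gte(sum(1L - labelsOf(part)), 1L)
  }
})

test_that("negative cases carry no systematic voxel signal", {
  spec <- tinyPhantomSpec(seed = 3L)
  set.seed(30)
  neg <- replicate(30, generateCase(spec, 0L), simplify = FALSE)
  m <- sapply(neg, function(cs) mean(viewData(caseViews(cs)[[1]])))
  # voxelwise mean difference between label-0 cases is centred on zero
  expect_lt(abs(mean(m[1:15]) - mean(m[16:30])), 0.1)
})

test_that("null worlds (amplitude 0) are label-free", {
  spec <- tinyPhantomSpec(seed = 4L, signalAmplitude = 0)
  set.seed(31)
  pos <- replicate(20, generateCase(spec, 1L), simplify = FALSE)
  neg <- replicate(20, generateCase(spec, 0L), simplify = FALSE)
  stat <- function(cs) mean(sapply(caseViews(cs), function(v) max(viewData(v))))
  sPos <- sapply(pos, stat); sNeg <- sapply(neg, stat)
  expect_lt(abs(mean(sPos) - mean(sNeg)), 3 * sd(c(sPos, sNeg)) / sqrt(10))
})

test_that("disjoint view windows render complementary lesion halves", {
  # informativeness (0.5, 0.5) with offsets 0 and 1/2 tile the azimuth:
  # each view renders about half the lesion's voxel mass, the union all
  spec <- phantomSpec(nViews = 2L, shape = c(12L, 24L, 24L), nCases = 10L,
                      signalAmplitude = 3, noiseSd = 0.5,
                      viewInformativeness = c(0.5, 0.5), seed = 5L)
  set.seed(32)
  pos <- generateCase(spec, 1L)
  neg <- withr::with_seed(32, generateCase(spec, 0L))
  # same RNG stream => identical background; difference isolates the lesion
  lesion <- lapply(1:2, function(v)
    viewData(caseViews(pos)[[v]]) - viewData(caseViews(neg)[[v]]))
  mass <- vapply(lesion, sum, numeric(1))
  union <- sum(pmax(lesion[[1]], lesion[[2]]))
  expect_gt(union, max(mass) * 1.5)          # pooled sees far more than one view
  expect_lt(sum(lesion[[1]] * lesion[[2]]), 1e-8)   # disjoint renderings
  expect_equal(mass[1] / (mass[1] + mass[2]), 0.5, tolerance = 0.25)
})

test_that("trained test AUC is non-decreasing in the planted signal amplitude", {
  # mean ordering over 3 seeds at 3 amplitudes (sampling error allowed in
  # the individual runs, not the means); small world for CPU budget
  tinyEnc <- encoderConfig(stemChannels = 2L, blockChannels = c(2L, 4L, 8L, 16L))
  aucAt <- function(A, sd) {
    spec <- phantomSpec(nViews = 2L, shape = c(8L, 16L, 16L), nCases = 150L,
                        signalAmplitude = A,
                        viewInformativeness = c(0.5, 0.5), seed = sd)
    split <- preprocessSplit(generateDataset(spec))
    cfg <- trainConfig(learningRate = 2e-3, epochs = 12L, batchSize = 16L,
                       weightDecay = 1e-3, seed = sd)
    m <- mvModel(viewIds(trainCases(split)[[1]]), tinyEnc,
                 "weighted_feature", seed = sd)
    m <- trainModel(m, split, cfg)
    auc(evaluateModel(m, testCases(split)))
  }
  means <- sapply(c(0, 1.5, 4), function(A)
    mean(sapply(1:3, function(sd) aucAt(A, sd))))
  expect_true(all(diff(means) >= 0))
})

test_that("oversized lesions are rejected", {
  spec <- phantomSpec(nViews = 1L, shape = c(2L, 8L, 8L), nCases = 10L,
                      viewInformativeness = 1, seed = 6L)
  set.seed(33)
  expect_error(
    replicate(50, generateCase(spec, 1L)),
    "larger than")
})
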