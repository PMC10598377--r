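# Reading, preprocessing and assembling multi-view volumetric inputs.

test_that("npy round trip preserves shape and values; readSliceStack validates rank", {
  x <- array(rnorm(5 * 9 * 11), c(5, 9, 11))
  p <- withr::local_tempfile(fileext = ".npy")
  writeNpy(x, p)
  expect_equal(readNpy(p), x, tolerance = 0)

  v <- readSliceStack(p, "sagT1")
  expect_s4_class(v, "ViewVolume")
  expect_identical(dim(v), c(5L, 9L, 11L))
  expect_identical(viewId(v), "sagT1")
  expect_equal(viewData(v), x)

  # MRNet-style stack: slices x 256 x 256, raw intensities preserved
  y <- array(seq_len(17 * 16 * 16) %% 7, c(17, 16, 16))
  p2 <- withr::local_tempfile(fileext = ".npy")
  writeNpy(y, p2)
  v2 <- readSliceStack(p2, "axial")
  expect_identical(dim(v2), c(17L, 16L, 16L))
  expect_equal(viewData(v2), y)

  p3 <- withr::local_tempfile(fileext = ".npy")
  writeNpy(matrix(0, 4, 4), p3)
  expect_error(readSliceStack(p3, "v"), "2-D")
})

test_that("npy reader handles C order, Fortran order and integer dtypes", {
  # hand-written C-order int16 file
  p <- withr::local_tempfile(fileext = ".npy")
  hdr <- "{'descr': '<i2', 'fortran_order': False, 'shape': (2, 3), }"
  pad <- (64 - (10 + nchar(hdr) + 1) %% 64) %% 64
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- file(p, "wb")
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 1, 0)), con)
  writeBin(nchar(hdr), con, size = 2, endian = "little")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.integer(1:6), con, size = 2, endian = "little")
  close(con)
  expect_equal(readNpy(p), matrix(1:6, 2, 3, byrow = TRUE))
})

test_that("preprocess crops the centre slices when the volume is too deep", {
  set.seed(1)
  x <- array(rnorm(61 * 8 * 8), c(61, 8, 8))
  v <- preprocessVolume(viewVolume("v", x), 32L, 8L)
  expect_identical(dim(v), c(32L, 8L, 8L))
  # centre 32 of 61: slices 15..46, then z-scored
  kept <- x[15:46, , ]
  expect_equal(viewData(v), (kept - mean(kept)) / sqrt(mean((kept - mean(kept))^2)),
               tolerance = 1e-12)
})

test_that("preprocess pads symmetrically with the extra slice at the end", {
  set.seed(2)
  x <- array(rnorm(17 * 8 * 8) + 5, c(17, 8, 8))
  v <- preprocessVolume(viewVolume("v", x), 32L, 8L)
  d <- viewData(v)
  expect_identical(dim(d), c(32L, 8L, 8L))
  expect_true(all(d[1:7, , ] == 0))      # 7 leading pad slices
  expect_true(all(d[25:32, , ] == 0))    # 8 trailing pad slices
  core <- d[8:24, , ]
  expect_lt(abs(mean(core)), 1e-10)
  expect_equal(sqrt(mean((core - mean(core))^2)), 1, tolerance = 1e-10)
})

test_that("preprocessed volumes are z-scored within 1e-4 and idempotent", {
  set.seed(3)
  for (D in c(10L, 17L, 40L)) {
    x <- array(rexp(D * 12 * 12), c(D, 12, 12))
    v1 <- preprocessVolume(viewVolume("v", x), 16L, 10L)
    d1 <- viewData(v1)
    if (D >= 16L) {   # no padding: plain z-score over everything
      expect_lt(abs(mean(d1)), 1e-4)
      expect_lt(abs(sqrt(mean((d1 - mean(d1))^2)) - 1), 1e-4)
    }
    v2 <- preprocessVolume(v1, 16L, 10L)
    expect_equal(viewData(v2), d1, tolerance = 1e-5)
  }
})

test_that("constant volumes normalise to zeros with a warning", {
  x <- array(7, c(4, 8, 8))
  expect_warning(v <- preprocessVolume(viewVolume("v", x), 4L, 8L),
                 "constant")
  expect_true(all(viewData(v) == 0))
})

test_that("in-plane resize interpolates bilinearly", {
  # doubling resolution of a linear ramp stays a linear ramp (interior)
  x <- array(rep(seq_len(8), each = 1), c(1, 8, 8))
  for (h in 1:8) x[1, h, ] <- h
  v <- preprocessVolume(viewVolume("v", x), 1L, 16L)
  d <- viewData(v)
  # interior rows must remain monotone with equal steps
  steps <- diff(d[1, 3:14, 1])
  expect_true(all(abs(steps - steps[1]) < 1e-8))
})

test_that("assembleCase enforces distinct ids, equal shapes and view order", {
  vol <- function(id) viewVolume(id, array(rnorm(4 * 8 * 8), c(4, 8, 8)))
  cs <- assembleCase(list(vol("a"), vol("b"), vol("c"), vol("d")), 1L, "p1")
  expect_identical(nViews(cs), 4L)
  expect_identical(caseLabel(cs), 1L)
  cs3 <- assembleCase(list(vol("a"), vol("b"), vol("c")), 0L, "p2")
  expect_identical(nViews(cs3), 3L)

  expect_error(assembleCase(list(vol("sagT1"), vol("sagT1")), 1L, "p3"),
               "sagT1")
  big <- viewVolume("b", array(0, c(5, 8, 8)))
  expect_error(assembleCase(list(vol("a"), big), 1L, "p4"), "differ")

  reord <- assembleCase(list(vol("b"), vol("a")), 1L, "p5",
                        viewOrder = c("a", "b"))
  expect_identical(viewIds(reord), c("a", "b"))
})

test_that("case manifest round trip reproduces shapes, labels and view order", {
  set.seed(4)
  spec <- tinyPhantomSpec()
  cases <- lapply(1:3, function(i) generateCase(spec, i %% 2L, paste0("c", i)))
  dir <- withr::local_tempdir()
  manifest <- exportCases(cases, dir)
  back <- readCaseManifest(manifest)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(caseId(back[[i]]), caseId(cases[[i]]))
    expect_identical(caseLabel(back[[i]]), caseLabel(cases[[i]]))
    expect_identical(viewIds(back[[i]]), viewIds(cases[[i]]))
    expect_equal(lapply(caseViews(back[[i]]), viewData),
                 lapply(caseViews(cases[[i]]), viewData))
  }
})

test_that("dataset export/import round-trips every partition", {
  spec <- tinyPhantomSpec(seed = 9L)
  split <- generateDataset(spec)
  dir <- withr::local_tempdir()
  exportDataset(split, dir)
  back <- importDataset(dir)
  expect_identical(length(trainCases(back)), length(trainCases(split)))
  expect_identical(labelsOf(testCases(back)), labelsOf(testCases(split)))
  expect_equal(viewData(caseViews(valCases(back)[[2]])[[1]]),
               viewData(caseViews(valCases(split)[[2]])[[1]]))
})
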