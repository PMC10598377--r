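# Shared fixtures: tiny architectures, tiny phantom worlds, and programmatic
# writers for DICOM / NIfTI files (all fixtures are generated at test time).

tinyEncoderConfig <- function() {
  encoderConfig(stemChannels = 2L, blockChannels = c(2L, 4L),
                blocksPerStage = c(1L, 1L), embeddingDim = 4L)
}

# Minimal phantom world for fast training smoke tests.
tinyPhantomSpec <- function(seed = 1L, ...) {
  phantomSpec(nViews = 2L, shape = c(8L, 12L, 12L), nCases = 16L,
              viewInformativeness = c(0.5, 0.5), seed = seed, ...)
}

tinyTrainConfig <- function(epochs = 2L, seed = 1L) {
  trainConfig(learningRate = 1e-3, epochs = epochs, batchSize = 8L,
              seed = seed)
}

trainTinyModel <- function(seed = 1L, strategy = "weighted_feature",
                           epochs = 2L, spec = tinyPhantomSpec(seed)) {
  split <- preprocessSplit(generateDataset(spec))
  model <- mvModel(viewIds(trainCases(split)[[1]])[seq_len(spec@nViews)],
                   tinyEncoderConfig(), strategy, seed = seed)
  list(model = trainModel(model, split, tinyTrainConfig(epochs, seed)),
       split = split)
}

labelsOf <- function(cases) vapply(cases, caseLabel, integer(1))

# ---- DICOM writer (explicit VR little endian, minimal attribute set) -------

dcmStringElem <- function(group, elem, vr, value) {
  val <- charToRaw(value)
  if (length(val) %% 2L == 1L)
    val <- c(val, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
    charToRaw(vr),
    writeBin(length(val), raw(), size = 2, endian = "little")[1:2],
    val)
}

dcmUSElem <- function(group, elem, value) {
  c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
    charToRaw("US"), as.raw(c(2L, 0L)),
    writeBin(as.integer(value), raw(), size = 2, endian = "little"))
}

dcmPixelElem <- function(pixels16) {
  val <- writeBin(as.integer(pixels16), raw(), size = 2, endian = "little")
  c(writeBin(c(0x7fe0L, 0x0010L), raw(), size = 2, endian = "little"),
    charToRaw("OW"), as.raw(c(0L, 0L)),
    writeBin(length(val), raw(), size = 4, endian = "little"),
    val)
}

# Write one slice; `slice` is a (rows x cols) matrix of small nonnegative
# integers. Optional instanceNumber / zPos control ordering attributes.
writeDicomSlice <- function(path, slice, seriesUid = "1.2.3.4",
                            instanceNumber = NULL, zPos = NULL) {
  meta <- c(dcmStringElem(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1"))
  body <- dcmStringElem(0x0020L, 0x000eL, "UI", seriesUid)
  if (!is.null(instanceNumber))
    body <- c(body, dcmStringElem(0x0020L, 0x0013L, "IS",
                                  as.character(instanceNumber)))
  if (!is.null(zPos))
    body <- c(body, dcmStringElem(0x0020L, 0x0032L, "DS",
                                  sprintf("0\\0\\%g", zPos)))
  body <- c(body,
            dcmUSElem(0x0028L, 0x0010L, nrow(slice)),
            dcmUSElem(0x0028L, 0x0011L, ncol(slice)),
            dcmUSElem(0x0028L, 0x0100L, 16L),
            dcmUSElem(0x0028L, 0x0103L, 0L),
            dcmPixelElem(as.integer(t(slice))))   # row-major pixel order
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

writeDicomSeriesDir <- function(dir, vol, shuffle = FALSE, zPos = TRUE,
                                instanceNumber = FALSE,
                                seriesUid = "1.2.3.4") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  D <- dim(vol)[1]
  ord <- if (shuffle) sample.int(D) else seq_len(D)
  for (i in seq_len(D)) {
    s <- ord[i]
    writeDicomSlice(file.path(dir, sprintf("f%02d.dcm", i)), vol[s, , ],
                    seriesUid = seriesUid,
                    instanceNumber = if (instanceNumber) s else NULL,
                    zPos = if (zPos) 2.5 * s else NULL)
  }
  invisible(dir)
}

# ---- NIfTI-1 writer (single .nii, float32 or int16) ------------------------

writeNiftiFile <- function(path, vol, datatype = 16L, slope = 0, inter = 0,
                           gz = FALSE) {
  d <- dim(vol)                       # (D,H,W) convention
  hdr <- raw(348)
  put <- function(off, x, size, what = "integer") {
    b <- writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
                  raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  put(0, 348L, 4)
  dims <- c(3L, d[3], d[2], d[1], 1L, 1L, 1L, 1L)   # nx,ny,nz = W,H,D
  put(40, dims, 2)
  put(70, datatype, 2)
  put(72, if (datatype == 16L) 32L else 16L, 2)     # bitpix
  put(108, 352, 4, "double")                        # vox_offset (float32)
  put(112, slope, 4, "double")
  put(116, inter, 4, "double")
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                             # extension flag
  vals <- as.numeric(aperm(vol, c(3, 2, 1)))        # x fastest
  if (datatype == 16L) {
    writeBin(vals, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(vals), con, size = 2, endian = "little")
  }
  invisible(path)
}
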