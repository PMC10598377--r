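# Minimal DICOM series reader: uncompressed little-endian transfer
# syntaxes (explicit VR 1.2.840.10008.1.2.1 and implicit VR
# 1.2.840.10008.1.2), single-frame grayscale slices. Only the attributes
# needed to assemble and order a volume are extracted; patient-identifying
# header fields are never parsed or retained, so a returned ViewVolume
# carries no protected health information.

EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
IMPLICIT_VR_LE <- "1.2.840.10008.1.2"

# VRs whose explicit-VR encoding uses a 2-byte reserved field + 4-byte
# length
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

u16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", 1L, size = 2L, signed = FALSE,
          endian = "little")
}
u32 <- function(raw, off) {
  # combine two u16 words: element lengths can exceed .Machine$integer.max/2
  u16(raw, off) + 65536 * u16(raw, off + 2L)
}

# Parse one DICOM file, returning the handful of attributes we need.
parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM part-10 file (missing DICM marker)",
                 path))
  pos <- 132L
  transfer <- EXPLICIT_VR_LE
  out <- list()
  wanted <- c("0020,000e" = "seriesUid", "0020,0013" = "instanceNumber",
              "0020,0032" = "imagePosition", "0028,0010" = "rows",
              "0028,0011" = "cols", "0028,0100" = "bitsAllocated",
              "0028,0103" = "pixelRepresentation",
              "0028,1052" = "rescaleIntercept", "0028,1053" = "rescaleSlope",
              "0002,0010" = "transferSyntax", "7fe0,0010" = "pixelData")
  while (pos + 8L <= length(raw)) {
    group <- u16(raw, pos)
    elem <- u16(raw, pos + 2L)
    inMeta <- group == 2L
    explicit <- inMeta || transfer == EXPLICIT_VR_LE
    if (explicit) {
      vr <- rawToChar(raw[(pos + 5):(pos + 6)])
      if (vr %in% LONG_VRS) {
        len <- u32(raw, pos + 8L)
        hdr <- 12L
      } else {
        len <- u16(raw, pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- ""
      len <- u32(raw, pos + 8L)
      hdr <- 8L
    }
    tag <- sprintf("%04x,%04x", group, elem)
    if (len == 4294967295) {                 # undefined length: skip to
      pos <- skipUndefined(raw, pos + hdr)   # sequence delimiter
      next
    }
    if (!is.na(idx <- match(tag, names(wanted)))) {
      field <- wanted[[idx]]
      val <- raw[(pos + hdr + 1):(pos + hdr + len)]
      if (field == "pixelData") {
        out$pixelDataRaw <- val
      } else if (field %in% c("rows", "cols", "bitsAllocated",
                              "pixelRepresentation")) {
        out[[field]] <- u16(val, 0L)
      } else {
        out[[field]] <- trimws(rawToChar(val[val != as.raw(0)]))
      }
      if (field == "transferSyntax") {
        transfer <- out$transferSyntax
        if (!transfer %in% c(EXPLICIT_VR_LE, IMPLICIT_VR_LE))
          stop(sprintf("'%s': unsupported transfer syntax '%s'", path,
                       transfer))
      }
    }
    pos <- pos + hdr + len
  }
  if (is.null(out$rows) || is.null(out$cols) || is.null(out$pixelDataRaw))
    stop(sprintf("'%s': missing Rows/Columns/PixelData", path))
  bits <- if (is.null(out$bitsAllocated)) 16L else out$bitsAllocated
  signed <- !is.null(out$pixelRepresentation) && out$pixelRepresentation == 1L
  px <- readBin(out$pixelDataRaw, "integer", out$rows * out$cols,
                size = bits %/% 8L,
                signed = if (bits == 32L) TRUE else signed,
                endian = "little")
  slope <- if (is.null(out$rescaleSlope)) 1 else as.numeric(out$rescaleSlope)
  inter <- if (is.null(out$rescaleIntercept)) 0 else
    as.numeric(out$rescaleIntercept)
  # PixelData is row-major (rows of the image in sequence)
  out$slice <- t(matrix(as.numeric(px) * slope + inter, nrow = out$cols))
  out$pixelDataRaw <- NULL
  out
}

# Skip an undefined-length sequence: advance to just past the sequence
# delimitation item (FFFE,E0DD).
skipUndefined <- function(raw, pos) {
  while (pos + 8L <= length(raw)) {
    if (u16(raw, pos) == 0xfffe && u16(raw, pos + 2L) == 0xe0dd)
      return(pos + 8L)
    pos <- pos + 2L
  }
  length(raw)
}

#' Read a DICOM series directory as a ViewVolume
#'
#' Reads every \code{.dcm} file (or every file, if none end in .dcm) in the
#' directory, checks that all slices belong to one series, sorts them by
#' the slice-position attribute (ImagePositionPatient z component, falling
#' back to InstanceNumber, falling back to filename order with a warning),
#' and stacks them into a \code{(depth, height, width)} volume. Sorting by
#' position makes the result invariant to the order in which files are
#' listed. Patient-identifying header fields are never read, so no
#' protected health information is retained in the returned object.
#'
#' @param dir directory containing one series of 2-D slices.
#' @param viewId view tag for the returned volume.
#' @return a \linkS4class{ViewVolume} with raw intensities.
#' @export
readDicomSeries <- function(dir, viewId) {
  files <- list.files(dir, full.names = TRUE)
  dcm <- files[grepl("\\.dcm$", files, ignore.case = TRUE)]
  if (length(dcm)) files <- dcm
  if (!length(files))
    stop(sprintf("no DICOM files found in '%s'", dir))
  slices <- lapply(files, parseDicomFile)
  uids <- unique(vapply(slices, function(s)
    if (is.null(s$seriesUid)) "" else s$seriesUid, character(1)))
  if (length(uids) > 1L)
    stop(sprintf("'%s' mixes %d series (SeriesInstanceUID values: %s)", dir,
                 length(uids), paste(uids, collapse = ", ")))
  zpos <- vapply(slices, function(s) {
    if (!is.null(s$imagePosition)) {
      as.numeric(strsplit(s$imagePosition, "\\\\")[[1]][3])
    } else NA_real_
  }, numeric(1))
  if (!anyNA(zpos)) {
    ord <- order(zpos)
  } else {
    inst <- vapply(slices, function(s) {
      if (is.null(s$instanceNumber)) NA_real_ else
        as.numeric(s$instanceNumber)
    }, numeric(1))
    if (!anyNA(inst)) {
      ord <- order(inst)
    } else {
      warning(sprintf(
        "'%s': no slice-position attribute; falling back to filename order",
        dir))
      ord <- order(basename(files))
    }
  }
  dims <- unique(t(vapply(slices, function(s) dim(s$slice), integer(2))))
  if (nrow(dims) > 1L)
    stop(sprintf("'%s': inconsistent slice sizes: %s", dir,
                 paste(apply(dims, 1, paste, collapse = "x"),
                       collapse = " vs ")))
  vol <- array(0, c(length(slices), dims[1, 1], dims[1, 2]))
  for (i in seq_along(ord)) vol[i, , ] <- slices[[ord[i]]]$slice
  viewVolume(viewId, vol)
}
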