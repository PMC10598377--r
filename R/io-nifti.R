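# Minimal NIfTI-1 reader (.nii / .nii.gz, single file). Handles both
# endiannesses and the common scalar datatypes, applies scl_slope/inter.
# No NIfTI package is available in the supported environment.

niftiDatatypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),   # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE),    # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE),    # int32
  `16` = list(what = "double", size = 4L, signed = TRUE),    # float32
  `64` = list(what = "double", size = 8L, signed = TRUE),    # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)) # uint16

#' Read a NIfTI-1 volume as a ViewVolume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) and
#' returns it in the package's \code{(depth, height, width)} axis
#' convention: the NIfTI z axis becomes depth (slices), y height, x width.
#' Only 3-D images (or 4-D with a single time point) are accepted.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param viewId view tag for the returned volume.
#' @return a \linkS4class{ViewVolume} with raw intensities (scaled by
#'   scl_slope/scl_inter when set; not z-scored).
#' @export
readNiftiVolume <- function(path, viewId) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L)
    stop(sprintf("'%s': truncated NIfTI header", path))
  readInt <- function(off, n, size, endian) {
    readBin(hdr[(off + 1):(off + n * size)], "integer", n, size = size,
            endian = endian)
  }
  endian <- "little"
  if (readInt(0L, 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (readInt(0L, 1L, 4L, endian) != 348L)
      stop(sprintf("'%s' is not a NIfTI-1 file (sizeof_hdr != 348)", path))
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("'%s' is not a NIfTI-1 file (magic '%s')", path, magic))
  dims <- readInt(40L, 8L, 2L, endian)
  ndim <- dims[1]
  if (ndim > 3L && all(dims[(4 + 1):(ndim + 1)] == 1L)) ndim <- 3L
  if (ndim != 3L)
    stop(sprintf("'%s': expected a 3-D image, header declares %d-D", path,
                 dims[1]))
  datatype <- readInt(70L, 1L, 2L, endian)
  dt <- niftiDatatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop(sprintf("'%s': unsupported NIfTI datatype code %d", path, datatype))
  voxOffset <- readBin(hdr[109:112], "double", 1L, size = 4L, endian = endian)
  slope <- readBin(hdr[113:116], "double", 1L, size = 4L, endian = endian)
  inter <- readBin(hdr[117:120], "double", 1L, size = 4L, endian = endian)
  skip <- round(voxOffset) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  n <- as.numeric(nx) * ny * nz
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n)
    stop(sprintf("'%s': truncated NIfTI data (expected %d voxels, read %d)",
                 path, n, length(vals)))
  vals <- as.numeric(vals)
  if (slope != 0 && !(slope == 1 && inter == 0)) vals <- vals * slope + inter
  vol <- aperm(array(vals, c(nx, ny, nz)), c(3, 2, 1))   # (z,y,x)=(D,H,W)
  viewVolume(viewId, vol)
}
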