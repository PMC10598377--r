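# Minimal NumPy .npy (format version 1.0) reader/writer. This is the
# portable binary array format of the stacked-slice per-view layout
# (one slices x 256 x 256 array per view per case). No R package for .npy
# is available in the supported environment, hence the small hand-rolled
# implementation.

NPY_MAGIC <- as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))  # \x93NUMPY

npyDtypes <- list(
  "<f8" = list(what = "double", size = 8L, signed = TRUE),
  "<f4" = list(what = "double", size = 4L, signed = TRUE),
  "<i4" = list(what = "integer", size = 4L, signed = TRUE),
  "<i2" = list(what = "integer", size = 2L, signed = TRUE),
  "<u2" = list(what = "integer", size = 2L, signed = FALSE),
  "|i1" = list(what = "integer", size = 1L, signed = TRUE),
  "|u1" = list(what = "integer", size = 1L, signed = FALSE))

#' Read a NumPy .npy array
#'
#' Supports format version 1.0, little-endian numeric dtypes (f4/f8,
#' i1/i2/i4, u1/u2), C- or Fortran-ordered. Returns an R array with the
#' numpy shape.
#'
#' @param path file path.
#' @return numeric array.
#' @export
readNpy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, NPY_MAGIC))
    stop(sprintf("'%s' is not a .npy file (bad magic)", path))
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  hlen <- if (ver[1] == 1L) {
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shapeStr <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  dt <- npyDtypes[[descr]]
  if (is.null(dt))
    stop(sprintf("unsupported .npy dtype '%s'", descr))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(vals) != n)
    stop(sprintf("truncated .npy: expected %d values, read %d", n,
                 length(vals)))
  vals <- as.numeric(vals)
  if (length(shape) <= 1L) return(vals)
  if (fortran) {
    array(vals, shape)
  } else {
    aperm(array(vals, rev(shape)), rev(seq_along(shape)))
  }
}

#' Write a NumPy .npy array
#'
#' Writes format version 1.0, dtype \code{<f8}, C order, so the file is
#' directly loadable by \code{numpy.load}.
#'
#' @param x numeric array (or vector).
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeNpy <- function(x, path) {
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  if (!is.null(dim(x)) && length(dim(x)) > 1L)
    x <- aperm(x, rev(seq_along(dim(x))))          # emit C order
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%s), }",
                    paste0(paste(shape, collapse = ", "),
                           if (length(shape) == 1L) "," else ""))
  # pad so that total header block length is a multiple of 64
  total <- 6L + 2L + 2L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(NPY_MAGIC, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}
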