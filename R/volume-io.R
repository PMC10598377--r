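#' Read a stacked-slice array file as a ViewVolume
#'
#' Loads one view stored as a single 3-D array (the per-view stacked-slice
#' layout: \code{slices x height x width}, e.g. one .npy file per view per
#' case). Intensities are returned as stored; no normalisation is applied.
#'
#' @param path path to a .npy array file.
#' @param viewId view tag for the returned volume.
#' @return a \linkS4class{ViewVolume} with depth = number of slices.
#' @export
readSliceStack <- function(path, viewId) {
  x <- readNpy(path)
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop(sprintf(
      "'%s': expected a 3-D slice stack, got a %d-D array", path,
      if (is.null(d)) 1L else length(d)))
  viewVolume(viewId, x)
}

# Bilinear in-plane resize of a (D, H, W) volume to (D, hw, hw), sampling
# at half-pixel centres (depth untouched).
resizeInPlane <- function(x, hw) {
  d <- dim(x)
  if (d[2] == hw && d[3] == hw) return(x)
  interpAxis <- function(nIn, nOut) {
    src <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
    src <- pmin(pmax(src, 0), nIn - 1)
    i0 <- floor(src)
    list(i0 = as.integer(i0) + 1L,
         i1 = pmin(as.integer(i0) + 2L, nIn),
         w1 = src - i0)
  }
  ih <- interpAxis(d[2], hw)
  iw <- interpAxis(d[3], hw)
  # gather the four corners for all output pixels at once
  xm <- matrix(x, nrow = d[1])                 # D x (H*W)
  colIdx <- function(hi, wi) rep(hi, times = hw) + d[2] * (rep(wi, each = hw) - 1L)
  wh1 <- rep(ih$w1, times = hw)
  ww1 <- rep(iw$w1, each = hw)
  g <- function(hi, wi) xm[, colIdx(hi, wi), drop = FALSE]
  ym <- g(ih$i0, iw$i0) * rep((1 - wh1) * (1 - ww1), each = d[1]) +
    g(ih$i1, iw$i0) * rep(wh1 * (1 - ww1), each = d[1]) +
    g(ih$i0, iw$i1) * rep((1 - wh1) * ww1, each = d[1]) +
    g(ih$i1, iw$i1) * rep(wh1 * ww1, each = d[1])
  array(ym, c(d[1], hw, hw))
}

#' Preprocess a view volume to a fixed shape
#'
#' In-plane resize (bilinear, half-pixel centres) to \code{targetHW x
#' targetHW}, per-volume z-score normalisation (population sd), and depth
#' harmonisation to \code{targetDepth}: volumes with too many slices are
#' symmetrically centre-cropped (extra slice removed at the end) before
#' normalisation; volumes with too few are symmetrically zero-padded after
#' normalisation (extra slice at the end), so padding sits exactly at the
#' mean. The z-score statistics are computed over non-pad voxels only:
#' leading/trailing all-zero slices are treated as padding, which makes the
#' operation idempotent.
#'
#' A constant-intensity volume (sd = 0) is normalised to all zeros with a
#' warning rather than an error.
#'
#' @param v a \linkS4class{ViewVolume}.
#' @param targetDepth target number of slices (>= 1).
#' @param targetHW target in-plane size (>= 8).
#' @return the preprocessed \linkS4class{ViewVolume} with shape
#'   \code{(targetDepth, targetHW, targetHW)}.
#' @export
preprocessVolume <- function(v, targetDepth, targetHW) {
  stopifnot(targetDepth >= 1L, targetHW >= 8L)
  x <- resizeInPlane(viewData(v), as.integer(targetHW))
  D <- dim(x)[1]
  if (D > targetDepth) {                       # symmetric centre-crop
    drop <- D - targetDepth
    lead <- drop %/% 2L
    x <- x[(lead + 1L):(lead + targetDepth), , , drop = FALSE]
    D <- targetDepth
  }
  # z-score over non-pad voxels (pad = leading/trailing all-zero slices)
  sliceZero <- apply(x == 0, 1, all)
  core <- seq_len(D)
  if (any(sliceZero) && !all(sliceZero)) {
    nonzero <- which(!sliceZero)
    core <- nonzero[1]:nonzero[length(nonzero)]
  }
  xc <- x[core, , , drop = FALSE]
  s <- sqrt(mean((xc - mean(xc))^2))
  if (s < 1e-12) {
    warning(sprintf("view '%s': constant intensity; normalised to zeros",
                    viewId(v)))
    x[] <- 0
  } else {
    x[core, , ] <- (xc - mean(xc)) / s
  }
  if (D < targetDepth) {                       # symmetric zero-pad
    add <- targetDepth - D
    lead <- add %/% 2L
    padded <- array(0, c(targetDepth, dim(x)[2], dim(x)[3]))
    padded[(lead + 1L):(lead + D), , ] <- x
    x <- padded
  }
  viewVolume(viewId(v), x)
}

#' Assemble preprocessed views into a case
#'
#' @param volumes list of \linkS4class{ViewVolume}, all preprocessed to the
#'   same shape, with distinct view ids.
#' @param label 0 or 1 (1 = positive class).
#' @param id case identifier.
#' @param viewOrder optional canonical view order (character); volumes are
#'   reordered to it. Defaults to the order given.
#' @return a \linkS4class{MultiViewCase}.
#' @export
assembleCase <- function(volumes, label, id, viewOrder = NULL) {
  ids <- vapply(volumes, viewId, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate view_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  shapes <- vapply(volumes, function(v) paste(dim(v), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) > 1L)
    stop(sprintf("view shapes differ: %s",
                 paste(unique(shapes), collapse = " vs ")))
  if (!is.null(viewOrder)) {
    ord <- match(viewOrder, ids)
    if (anyNA(ord))
      stop(sprintf("missing view(s): %s",
                   paste(viewOrder[is.na(ord)], collapse = ", ")))
    volumes <- volumes[ord]
  }
  new("MultiViewCase", caseId = as.character(id), views = volumes,
      label = as.integer(label))
}

#' Write cases as stacked-slice arrays plus a CSV manifest
#'
#' Each view of each case is written as \code{<case>_<view>.npy}; the
#' manifest has columns \code{case_id}, \code{label}, then one path column
#' per view in canonical order. Reading the manifest back reproduces
#' shapes, labels and view order exactly.
#'
#' @param cases list of \linkS4class{MultiViewCase} sharing one view order.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
exportCases <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vids <- viewIds(cases[[1]])
  rows <- lapply(cases, function(cs) {
    if (!identical(viewIds(cs), vids))
      stop(sprintf("case '%s' has view order %s; expected %s", caseId(cs),
                   paste(viewIds(cs), collapse = ","),
                   paste(vids, collapse = ",")))
    paths <- vapply(caseViews(cs), function(v) {
      fn <- sprintf("%s_%s.npy", caseId(cs), viewId(v))
      writeNpy(viewData(v), file.path(dir, fn))
      fn
    }, character(1))
    c(case_id = caseId(cs), label = caseLabel(cs), paths)
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("case_id", "label", vids)
  manifest <- file.path(dir, "manifest.csv")
  write.csv(df, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read cases from a manifest written by exportCases
#'
#' The canonical view order is the manifest's column order (never the
#' filesystem order).
#'
#' @param manifest path to a manifest.csv.
#' @return list of \linkS4class{MultiViewCase}.
#' @export
readCaseManifest <- function(manifest) {
  df <- read.csv(manifest, check.names = FALSE,
                 colClasses = "character")
  need <- c("case_id", "label")
  if (!all(need %in% names(df)))
    stop(sprintf("manifest '%s' lacks column(s): %s", manifest,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  vids <- setdiff(names(df), need)
  if (!length(vids)) stop("manifest has no view columns")
  base <- dirname(manifest)
  lapply(seq_len(nrow(df)), function(i) {
    vols <- lapply(vids, function(vid)
      readSliceStack(file.path(base, df[[vid]][i]), vid))
    assembleCase(vols, as.integer(df$label[i]), df$case_id[i])
  })
}

#' Export / import a full DatasetSplit
#'
#' Writes (or reads) the train/validation/test partitions into
#' subdirectories, each with its own stacked-slice arrays and manifest.
#'
#' @param split a \linkS4class{DatasetSplit}.
#' @param dir dataset directory.
#' @return \code{exportDataset}: \code{dir}, invisibly;
#'   \code{importDataset}: a \linkS4class{DatasetSplit}.
#' @export
exportDataset <- function(split, dir) {
  exportCases(trainCases(split), file.path(dir, "train"))
  exportCases(valCases(split), file.path(dir, "validation"))
  exportCases(testCases(split), file.path(dir, "test"))
  invisible(dir)
}

#' @rdname exportDataset
#' @export
importDataset <- function(dir) {
  datasetSplit(readCaseManifest(file.path(dir, "train", "manifest.csv")),
               readCaseManifest(file.path(dir, "validation", "manifest.csv")),
               readCaseManifest(file.path(dir, "test", "manifest.csv")))
}
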