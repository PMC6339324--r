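# Calibration from TIFF page attributes (as returned by tiff::readTIFF with
# info = TRUE). Returns NULL when no usable resolution tag is present.
# ImageJ-style TIFFs without a resolution unit store pixels per micrometre;
# "inch" and "cm" units are converted.
.calibrationFromTiffAttrs <- function(attrs, sliceSpacingZ = 1.51) {
  xres <- attrs[["x.resolution"]]
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  unit <- attrs[["resolution.unit"]]
  umPerPx <- if (is.null(unit) || identical(unit, "none")) 1 / xres
             else if (identical(unit, "inch")) 25400 / xres
             else if (identical(unit, "cm")) 10000 / xres
             else return(NULL)
  Calibration(pixelSizeXY = umPerPx, sliceSpacingZ = sliceSpacingZ)
}

#' Read a multi-page grayscale TIFF as a calibrated Z-stack
#'
#' Pages become Z slices (first page = first slice). 8- and 16-bit grayscale
#' images are supported; intensities are kept on their native integer scale.
#' If the file carries an X-resolution tag the calibration is derived from
#' it (ImageJ convention: pixels per micrometre when no unit is set);
#' an explicit `calibration` argument always wins, and without either the
#' default 0.6 um/px acquisition calibration is used.
#'
#' @param path TIFF file path.
#' @param calibration optional [Calibration-class] override.
#' @return a [ZStack-class].
#' @export
readStack <- function(path, calibration = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty TIFF: ", path)
  if (length(dim(pages[[1]])) != 2L)
    stop("expected single-channel grayscale TIFF: ", path)
  bits <- attr(pages[[1]], "bits.per.sample")
  bitDepth <- if (!is.null(bits) && bits == 16L) 16L else 8L
  if (is.null(calibration))
    calibration <- .calibrationFromTiffAttrs(attributes(pages[[1]]))
  if (is.null(calibration)) calibration <- Calibration()
  d <- dim(pages[[1]])
  vox <- array(0, dim = c(d[1], d[2], length(pages)))
  for (z in seq_along(pages)) {
    if (!identical(dim(pages[[z]]), d)) stop("slices differ in shape: ", path)
    vox[, , z] <- pages[[z]]
  }
  ZStack(vox, calibration, bitDepth)
}

#' Write a Z-stack as a multi-page TIFF
#'
#' Intensities are stored at the stack's native bit depth. Note that the
#' writer cannot embed resolution tags; calibration travels in the run
#' manifest instead.
#'
#' @param stack a [ZStack-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ZStack"))
  vmax <- 2^bitDepth(stack) - 1
  pages <- lapply(seq_len(nSlices(stack)),
                  function(z) voxels(stack)[, , z] / vmax)
  tiff::writeTIFF(pages, path, bits.per.sample = bitDepth(stack),
                  compression = "none")
  invisible(path)
}

#' Read and write label masks as 16-bit TIFF
#'
#' Labels are stored verbatim as 16-bit gray values (0 = background), the
#' interchange format for instance masks in common image-analysis suites.
#'
#' @param mask a [LabelMask-class].
#' @param path file path.
#' @param calibration optional [Calibration-class] for reading (default
#'   taken from resolution tags, else the package default).
#' @return `writeLabelMask`: `path`, invisibly; `readLabelMask`: a
#'   [LabelMask-class].
#' @export
writeLabelMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  if (nObjects(mask) > 65535L) stop("more than 65535 labels do not fit 16-bit")
  tiff::writeTIFF(pixels(mask) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path, calibration = NULL) {
  page <- tiff::readTIFF(path, all = FALSE, info = TRUE, as.is = TRUE)
  if (is.null(calibration))
    calibration <- .calibrationFromTiffAttrs(attributes(page))
  if (is.null(calibration)) calibration <- Calibration()
  m <- matrix(as.integer(page), nrow(page), ncol(page))
  LabelMask(m, calibration)
}

#' Write a red-outline overlay PNG
#'
#' Renders a grayscale base image (e.g. the SD projection or a brightfield
#' image) with the outlines of the segmented cells drawn in red, mirroring
#' the usual visual check of a segmentation run. Requires the `png` package.
#'
#' @param base a [ProjectedImage-class] used as the grayscale backdrop.
#' @param labels a [LabelMask-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeOverlay <- function(base, labels, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for overlays")
  stopifnot(is(base, "ProjectedImage"), is(labels, "LabelMask"))
  g <- pixels(base)
  rng <- range(g)
  g <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  lab <- pixels(labels)
  edge <- .labelBoundaries(lab)
  rgb <- array(0, dim = c(nrow(g), ncol(g), 3))
  rgb[, , 1] <- ifelse(edge, 1, g)
  rgb[, , 2] <- ifelse(edge, 0, g)
  rgb[, , 3] <- ifelse(edge, 0, g)
  png::writePNG(rgb, path)
  invisible(path)
}

# boundary pixels of a label image: labelled pixels with a 4-neighbour of a
# different value
.labelBoundaries <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  p <- matrix(-1L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- lab
  ctr <- p[2:(nr + 1L), 2:(nc + 1L)]
  diff <- (p[1:nr, 2:(nc + 1L)] != ctr) | (p[3:(nr + 2L), 2:(nc + 1L)] != ctr) |
          (p[2:(nr + 1L), 1:nc] != ctr) | (p[2:(nr + 1L), 3:(nc + 2L)] != ctr)
  ctr > 0L & diff
}

#' Export per-cell boundary point sets
#'
#' Writes one CSV with the boundary pixels of every cell (columns `label`,
#' `row`, `col`, pixel coordinates), a plain-text stand-in for binary ROI
#' archives that downstream tools can ingest.
#'
#' @param labels a [LabelMask-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRoiBoundaries <- function(labels, path) {
  stopifnot(is(labels, "LabelMask"))
  lab <- pixels(labels)
  edge <- .labelBoundaries(lab)
  idx <- which(edge, arr.ind = TRUE)
  df <- data.frame(label = lab[edge], row = idx[, 1], col = idx[, 2])
  df <- df[order(df$label, df$row, df$col), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
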