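#' Threshold the background-subtracted image into a cytosol mask
#'
#' After the double background subtraction the background is close to zero,
#' so a fixed gray-value threshold (default 1) suffices to highlight
#' complete cell bodies and nuclei. Pixels at or above the threshold are
#' foreground.
#'
#' @param img output of [subtractBackground()], a [ProjectedImage-class].
#' @param params a [SegmentationParams-class] (uses `cytosolThreshold`).
#' @return a [BinaryMask-class].
#' @export
thresholdCytosol <- function(img, params = segmentationParams()) {
  stopifnot(is(img, "ProjectedImage"), is(params, "SegmentationParams"))
  BinaryMask(pixels(img) >= params@cytosolThreshold, calibration(img))
}

#' Detect watershed seeds as intensity maxima of given prominence
#'
#' Local maxima whose topographic prominence is at least `tolerance` become
#' seeds; equal-valued plateau maxima are merged into a single seed. This
#' follows the Find-Maxima "noise tolerance" semantics: a peak is discarded
#' when it can be reached from a higher peak without descending more than
#' the tolerance.
#'
#' @param img a [ProjectedImage-class] (typically the blurred watershed copy).
#' @param tolerance minimum prominence in gray levels (> 0).
#' @return a [LabelMask-class] with one single-pixel seed per accepted
#'   maximum, labelled in decreasing peak height.
#' @export
findSeeds <- function(img, tolerance) {
  stopifnot(is(img, "ProjectedImage"), is.finite(tolerance), tolerance > 0)
  LabelMask(find_seeds_cpp(pixels(img), tolerance), calibration(img))
}

#' Seeded watershed tessellation of an intensity image
#'
#' Grows one basin downhill from every seed (Meyer's flooding on the negated
#' image, 8-connected) until basins meet; meeting pixels become watershed
#' line (label 0). Every non-line pixel of the frame is assigned to a basin,
#' and no two pixels of different basins are 8-adjacent.
#'
#' @param img a [ProjectedImage-class] whose maxima the seeds mark.
#' @param seeds a [LabelMask-class] of seed markers (e.g. from [findSeeds()]).
#' @return a [LabelMask-class] of basins; 0 marks watershed lines.
#' @export
watershedBasins <- function(img, seeds) {
  stopifnot(is(img, "ProjectedImage"), is(seeds, "LabelMask"))
  if (!identical(dim(img), dim(seeds))) stop("image and seeds differ in shape")
  LabelMask(watershed_cpp(-pixels(img), pixels(seeds)), calibration(img))
}

#' Watershed splitting mask ("segmented particles")
#'
#' Reproduces the maxima-seeded watershed split of touching cells: the
#' background-subtracted image is blurred with the watershed sigma, the seed
#' prominence is set to `noiseMultiplier` times the mean of the strictly
#' positive pixels of that blurred copy, and a seeded watershed tessellates
#' the frame. The returned mask is foreground everywhere except on the
#' watershed lines, i.e. a binary image of lines that split touching cells.
#'
#' An image without positive pixels yields no seeds; the mask is then
#' all-foreground (no lines) and a message is emitted.
#'
#' @param img output of [subtractBackground()], a [ProjectedImage-class].
#' @param params a [SegmentationParams-class].
#' @return a [BinaryMask-class]; `TRUE` except on dividing lines.
#' @export
segmentedParticles <- function(img, params = segmentationParams()) {
  stopifnot(is(img, "ProjectedImage"), is(params, "SegmentationParams"))
  blurred <- gaussianBlurPhysical(img, params@sigmaWatershed)
  bp <- pixels(blurred)
  pos <- bp[bp > 0]
  if (length(pos) == 0L) {
    message("segmentedParticles: no positive pixels; returning mask without lines")
    return(BinaryMask(matrix(TRUE, nrow(bp), ncol(bp)), calibration(img)))
  }
  tol <- params@noiseMultiplier * mean(pos)
  seeds <- findSeeds(blurred, tol)
  if (nObjects(seeds) == 0L) {
    message("segmentedParticles: no maxima above tolerance; returning mask without lines")
    return(BinaryMask(matrix(TRUE, nrow(bp), ncol(bp)), calibration(img)))
  }
  basins <- watershedBasins(blurred, seeds)
  BinaryMask(pixels(basins) > 0L, calibration(img))
}

#' Pixel-wise AND of two binary masks
#'
#' Combines the cytosol mask with the watershed splitting mask, yielding a
#' binary image of the cell population in which juxtaposed cell borders are
#' separated by the watershed lines.
#'
#' @param cytosol,particles [BinaryMask-class] objects on the same grid.
#' @return a [BinaryMask-class].
#' @export
combineAnd <- function(cytosol, particles) {
  stopifnot(is(cytosol, "BinaryMask"), is(particles, "BinaryMask"))
  if (!identical(dim(cytosol), dim(particles)))
    stop("masks differ in shape")
  BinaryMask(pixels(cytosol) & pixels(particles), calibration(cytosol))
}

#' Label connected components and filter by physical size
#'
#' Labels 8-connected foreground components, drops every component whose
#' area is not strictly bigger than `minArea` (in square micrometres,
#' converted through the calibration) to avoid detection of cell debris, and
#' relabels the survivors `1..K` in raster-scan order of their first pixel.
#'
#' @param mask a [BinaryMask-class].
#' @param params a [SegmentationParams-class] (uses `minArea`).
#' @return a [LabelMask-class].
#' @export
sizeFilterLabel <- function(mask, params = segmentationParams()) {
  stopifnot(is(mask, "BinaryMask"), is(params, "SegmentationParams"))
  lab <- label_components_cpp(pixels(mask), 8L)
  k <- max(lab)
  if (k == 0L) return(LabelMask(lab, calibration(mask)))
  minPx <- um2ToPx2(params@minArea, calibration(mask))
  areas <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(areas > minPx)           # strictly bigger than minArea
  remap <- integer(k)
  remap[keep] <- seq_along(keep)         # original order is raster order
  out <- lab
  out[out > 0L] <- remap[out[out > 0L]]
  LabelMask(out, calibration(mask))
}

#' Remove labels that touch the image border
#'
#' Mirrors manual counting protocols that only consider cells completely
#' contained in the image. Surviving labels are renumbered `1..K` preserving
#' raster order.
#'
#' @param labels a [LabelMask-class].
#' @return a [LabelMask-class] without edge-touching objects.
#' @export
excludeEdgeObjects <- function(labels) {
  stopifnot(is(labels, "LabelMask"))
  px <- pixels(labels)
  k <- nObjects(labels)
  if (k == 0L) return(labels)
  edge <- unique(c(px[1, ], px[nrow(px), ], px[, 1], px[, ncol(px)]))
  edge <- edge[edge > 0L]
  keep <- setdiff(seq_len(k), edge)
  remap <- integer(k)
  remap[keep] <- seq_along(keep)
  out <- px
  out[out > 0L] <- remap[out[out > 0L]]
  LabelMask(out, calibration(labels))
}

#' Full segmentation pipeline: Z-stack to cell label mask
#'
#' Runs the complete chain: SD projection, double background subtraction,
#' cytosol thresholding and maxima-seeded watershed in parallel, pixel-wise
#' AND, and size filtering. Deterministic for a fixed input and parameter
#' set.
#'
#' @param stack a [ZStack-class].
#' @param params a [SegmentationParams-class].
#' @param excludeEdges drop cells touching the image border (default FALSE).
#' @return a [LabelMask-class] of segmented cells.
#' @examples
#' sc <- generateScene(sceneParams(nCells = 3, fieldSize = c(160, 160), seed = 7))
#' nObjects(segmentCells(sc$stack))
#' @export
segmentCells <- function(stack, params = segmentationParams(),
                         excludeEdges = FALSE) {
  stopifnot(is(stack, "ZStack"), is(params, "SegmentationParams"))
  proj <- sdProjection(stack, params@sdDenominator)
  flat <- subtractBackground(proj, params)
  cyt <- thresholdCytosol(flat, params)
  part <- segmentedParticles(flat, params)
  lab <- sizeFilterLabel(combineAnd(cyt, part), params)
  if (excludeEdges) lab <- excludeEdgeObjects(lab)
  lab
}
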