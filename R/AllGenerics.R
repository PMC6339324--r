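#' Accessors for LeakySeg containers
#'
#' `pixels()` returns the raw matrix of a 2-D container (numeric for
#' [ProjectedImage-class], logical for [BinaryMask-class], integer for
#' [LabelMask-class]); `voxels()` the 3-D array of a [ZStack-class];
#' `calibration()` the [Calibration-class]; `pixelSize()` the lateral pixel
#' size in um; `bitDepth()` and `nSlices()` the stack properties; and
#' `nObjects()` the number of labels in a [LabelMask-class].
#'
#' @param x a LeakySeg container.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname accessors
setMethod("pixels", "ProjectedImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixels", "BinaryMask", function(x) x@pixels)
#' @rdname accessors
setMethod("pixels", "LabelMask", function(x) x@pixels)
#' @rdname accessors
setMethod("voxels", "ZStack", function(x) x@voxels)

#' @rdname accessors
setMethod("calibration", "ZStack", function(x) x@calibration)
#' @rdname accessors
setMethod("calibration", "ProjectedImage", function(x) x@calibration)
#' @rdname accessors
setMethod("calibration", "BinaryMask", function(x) x@calibration)
#' @rdname accessors
setMethod("calibration", "LabelMask", function(x) x@calibration)

#' @rdname accessors
setMethod("pixelSize", "Calibration", function(x) x@pixelSizeXY)
#' @rdname accessors
setMethod("pixelSize", "ZStack", function(x) x@calibration@pixelSizeXY)
#' @rdname accessors
setMethod("pixelSize", "ProjectedImage", function(x) x@calibration@pixelSizeXY)
#' @rdname accessors
setMethod("pixelSize", "BinaryMask", function(x) x@calibration@pixelSizeXY)
#' @rdname accessors
setMethod("pixelSize", "LabelMask", function(x) x@calibration@pixelSizeXY)

#' @rdname accessors
setMethod("bitDepth", "ZStack", function(x) x@bitDepth)
#' @rdname accessors
setMethod("nSlices", "ZStack", function(x) dim(x@voxels)[3])
#' @rdname accessors
setMethod("nObjects", "LabelMask", function(x) {
  if (length(x@pixels) == 0L) 0L else max(x@pixels)
})

#' @rdname accessors
#' @export
setMethod("dim", "ZStack", function(x) dim(x@voxels))
#' @rdname accessors
#' @export
setMethod("dim", "ProjectedImage", function(x) dim(x@pixels))
#' @rdname accessors
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@pixels))
#' @rdname accessors
#' @export
setMethod("dim", "LabelMask", function(x) dim(x@pixels))

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %.4g um/px (XY), %.4g um slice spacing (Z)\n",
              object@pixelSizeXY, object@sliceSpacingZ))
})

setMethod("show", "ZStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ZStack: %d x %d px, %d slices, %d-bit\n", d[1], d[2], d[3],
              object@bitDepth))
  show(object@calibration)
})

setMethod("show", "ProjectedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ProjectedImage: %d x %d px, range [%.3g, %.3g]\n",
              d[1], d[2], min(object@pixels), max(object@pixels)))
  show(object@calibration)
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px, %d foreground px (%.1f%%)\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels),
              100 * mean(object@pixels)))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d x %d px, %d objects\n",
              nrow(object@pixels), ncol(object@pixels), nObjects(object)))
})

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams:\n")
  cat(sprintf("  cap multiplier        %.3g x global mean\n", object@capMultiplier))
  cat(sprintf("  background sigma      %.3g um\n", object@sigmaBackground))
  cat(sprintf("  rolling-ball radius   %.3g um\n", object@rollingBallRadius))
  cat(sprintf("  smoothing sigma       %.3g um\n", object@sigmaSmooth))
  cat(sprintf("  watershed sigma       %.3g um\n", object@sigmaWatershed))
  cat(sprintf("  cytosol threshold     %.3g gray\n", object@cytosolThreshold))
  cat(sprintf("  noise multiplier      %.3g x mean of positives\n",
              object@noiseMultiplier))
  cat(sprintf("  min area              %.3g um^2 (strictly bigger than)\n",
              object@minArea))
  cat(sprintf("  SD denominator        %s\n", object@sdDenominator))
})

setMethod("show", "MatchTable", function(object) {
  cat(sprintf("MatchTable: %d truth x %d predicted objects, %d overlapping pairs\n",
              nrow(object@overlap), ncol(object@overlap),
              sum(object@overlap > 0)))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:\n")
  cat(sprintf("  manually counted    %d\n", object@manuallyCounted))
  cat(sprintf("  correctly segmented %d\n", object@correctlySegmented))
  cat(sprintf("  missed              %d\n", object@missed))
  cat(sprintf("  under-segmented     %d\n", object@underSegmented))
  cat(sprintf("  over-segmented      %d\n", object@overSegmented))
  cat(sprintf("  debris (FP)         %d\n", object@debris))
  cat(sprintf("  TP / FP / FN        %d / %d / %d\n", object@truePositives,
              object@falsePositives, object@falseNegatives))
  cat(sprintf("  accuracy            %.1f%%\n", object@accuracy))
  cat(sprintf("  sensitivity         %.1f%%\n", object@sensitivity))
  cat(sprintf("  percent correct     %.1f%%\n", object@percentCorrect))
  cat(sprintf("  mean IoU            %.3f\n", object@meanIoU))
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf("SceneParams: %d cells on %d x %d px (%.3g um/px), %d slices, seed %d\n",
              object@nCells, object@fieldSize[1], object@fieldSize[2],
              object@pixelSize, object@nSlices, object@seed))
})
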