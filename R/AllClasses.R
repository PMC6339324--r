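#' @useDynLib LeakySeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Physical calibration of an image grid
#'
#' Holds the lateral pixel size and the axial slice spacing of a confocal
#' acquisition, both in micrometres. The lateral pixel size drives every
#' conversion between physical parameters (blur sigmas, rolling-ball radius,
#' minimum cell area) and pixel units; the slice spacing is informational.
#'
#' @slot pixelSizeXY lateral sampling, micrometres per pixel (> 0).
#' @slot sliceSpacingZ axial slice spacing in micrometres (> 0).
#'
#' @examples
#' Calibration()                      # the default 0.6 um/px, 1.51 um slices
#' Calibration(pixelSizeXY = 0.3)
#' @export
setClass("Calibration",
  representation(pixelSizeXY = "numeric", sliceSpacingZ = "numeric"),
  prototype(pixelSizeXY = 0.6, sliceSpacingZ = 1.51)
)

setValidity("Calibration", function(object) {
  if (length(object@pixelSizeXY) != 1L || !is.finite(object@pixelSizeXY) ||
      object@pixelSizeXY <= 0)
    return("pixelSizeXY must be a single positive number (um/px)")
  if (length(object@sliceSpacingZ) != 1L || !is.finite(object@sliceSpacingZ) ||
      object@sliceSpacingZ <= 0)
    return("sliceSpacingZ must be a single positive number (um)")
  TRUE
})

#' @param pixelSizeXY lateral pixel size in micrometres per pixel.
#' @param sliceSpacingZ axial slice spacing in micrometres.
#' @rdname Calibration-class
#' @export
Calibration <- function(pixelSizeXY = 0.6, sliceSpacingZ = 1.51) {
  new("Calibration", pixelSizeXY = pixelSizeXY, sliceSpacingZ = sliceSpacingZ)
}

#' Calibrated confocal Z-stack
#'
#' A 3-D grayscale intensity array (rows x cols x slices) as acquired, with
#' its physical calibration and nominal bit depth. Intensities must lie in
#' `[0, 2^bitDepth - 1]`.
#'
#' @slot voxels numeric 3-D array, dimensions rows x cols x slices.
#' @slot calibration a [Calibration-class] object.
#' @slot bitDepth integer, 8 or 16.
#' @export
setClass("ZStack",
  representation(voxels = "array", calibration = "Calibration",
                 bitDepth = "integer")
)

setValidity("ZStack", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3-D array (rows x cols x slices)")
  if (d[3] < 1L) return("a stack needs at least one slice")
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  v <- object@voxels
  if (anyNA(v) || any(v < 0) || any(v > 2^object@bitDepth - 1))
    return("intensities must lie within [0, 2^bitDepth - 1]")
  TRUE
})

#' @param voxels numeric 3-D array (rows x cols x slices).
#' @param calibration a [Calibration-class] object.
#' @param bitDepth 8 or 16.
#' @rdname ZStack-class
#' @export
ZStack <- function(voxels, calibration = Calibration(), bitDepth = 8L) {
  new("ZStack", voxels = voxels, calibration = calibration,
      bitDepth = as.integer(bitDepth))
}

#' Calibrated 2-D floating-point image
#'
#' The working representation of the pipeline: everything downstream of the
#' standard-deviation projection is held as a real-valued matrix plus the
#' calibration carried over from the source stack.
#'
#' @slot pixels numeric matrix of intensities (finite).
#' @slot calibration a [Calibration-class] object.
#' @export
setClass("ProjectedImage",
  representation(pixels = "matrix", calibration = "Calibration")
)

setValidity("ProjectedImage", function(object) {
  if (!is.numeric(object@pixels)) return("pixels must be a numeric matrix")
  if (any(!is.finite(object@pixels))) return("pixels must be finite")
  TRUE
})

#' @param pixels numeric matrix.
#' @param calibration a [Calibration-class] object.
#' @rdname ProjectedImage-class
#' @export
ProjectedImage <- function(pixels, calibration = Calibration()) {
  storage.mode(pixels) <- "double"
  new("ProjectedImage", pixels = pixels, calibration = calibration)
}

#' Binary foreground mask on a calibrated grid
#'
#' @slot pixels logical matrix; `TRUE` marks foreground.
#' @slot calibration a [Calibration-class] object.
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", calibration = "Calibration")
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
  if (anyNA(object@pixels)) return("pixels must not contain NA")
  TRUE
})

#' @param pixels logical matrix.
#' @param calibration a [Calibration-class] object.
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(pixels, calibration = Calibration()) {
  new("BinaryMask", pixels = pixels, calibration = calibration)
}

#' Integer-labelled object map
#'
#' Each segmented object's pixels share one positive integer ID; background
#' is 0. Labels produced by the pipeline are consecutive `1..K` in
#' raster-scan order of each object's first pixel, and each object is
#' 8-connected.
#'
#' @slot pixels integer matrix of labels (>= 0).
#' @slot calibration a [Calibration-class] object.
#' @export
setClass("LabelMask",
  representation(pixels = "matrix", calibration = "Calibration")
)

setValidity("LabelMask", function(object) {
  if (!is.integer(object@pixels)) return("pixels must be an integer matrix")
  if (anyNA(object@pixels) || any(object@pixels < 0L))
    return("labels must be non-negative integers")
  TRUE
})

#' @param pixels integer matrix (0 = background).
#' @param calibration a [Calibration-class] object.
#' @rdname LabelMask-class
#' @export
LabelMask <- function(pixels, calibration = Calibration()) {
  storage.mode(pixels) <- "integer"
  new("LabelMask", pixels = pixels, calibration = calibration)
}

#' Tunable constants of the segmentation pipeline
#'
#' Every tunable of the processing scheme, expressed in physical units so the
#' same parameter set transfers across magnifications. Defaults reproduce the
#' published processing chain for DRAQ5-stained adherent cells.
#'
#' @slot capMultiplier cap for the background image: intensities above
#'   `capMultiplier * mean(image)` are clipped (dimensionless, default 3).
#' @slot sigmaBackground Gaussian sigma of the background image blur, um
#'   (default 100).
#' @slot rollingBallRadius rolling-ball radius for flattening, um (default 100;
#'   chosen larger than a cell radius so cytosolic signal is untouched).
#' @slot sigmaSmooth Gaussian sigma applied after the rolling ball, um
#'   (default 1).
#' @slot sigmaWatershed Gaussian sigma of the watershed input copy, um
#'   (default 2).
#' @slot cytosolThreshold gray-value threshold of the cytosol mask (default 1).
#' @slot noiseMultiplier seed prominence = `noiseMultiplier * mean` of the
#'   strictly positive pixels of the blurred image (dimensionless, default 3).
#' @slot minArea minimum object area in um^2; objects must be strictly bigger
#'   to survive (default 200).
#' @slot sdDenominator `"n-1"` (sample SD, default) or `"n"` for the
#'   Z-projection.
#' @export
setClass("SegmentationParams",
  representation(capMultiplier = "numeric", sigmaBackground = "numeric",
                 rollingBallRadius = "numeric", sigmaSmooth = "numeric",
                 sigmaWatershed = "numeric", cytosolThreshold = "numeric",
                 noiseMultiplier = "numeric", minArea = "numeric",
                 sdDenominator = "character"),
  prototype(capMultiplier = 3, sigmaBackground = 100, rollingBallRadius = 100,
            sigmaSmooth = 1, sigmaWatershed = 2, cytosolThreshold = 1,
            noiseMultiplier = 3, minArea = 200, sdDenominator = "n-1")
)

setValidity("SegmentationParams", function(object) {
  pos <- c(capMultiplier = object@capMultiplier,
           sigmaBackground = object@sigmaBackground,
           rollingBallRadius = object@rollingBallRadius,
           sigmaSmooth = object@sigmaSmooth,
           sigmaWatershed = object@sigmaWatershed,
           noiseMultiplier = object@noiseMultiplier,
           minArea = object@minArea)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("all multipliers, sigmas, radii and areas must be positive")
  if (!is.finite(object@cytosolThreshold) || object@cytosolThreshold < 0)
    return("cytosolThreshold must be >= 0")
  if (!object@sdDenominator %in% c("n-1", "n"))
    return('sdDenominator must be "n-1" or "n"')
  TRUE
})

#' @param capMultiplier,sigmaBackground,rollingBallRadius,sigmaSmooth
#'   see slot documentation.
#' @param sigmaWatershed,cytosolThreshold,noiseMultiplier,minArea,sdDenominator
#'   see slot documentation.
#' @rdname SegmentationParams-class
#' @export
segmentationParams <- function(capMultiplier = 3, sigmaBackground = 100,
                               rollingBallRadius = 100, sigmaSmooth = 1,
                               sigmaWatershed = 2, cytosolThreshold = 1,
                               noiseMultiplier = 3, minArea = 200,
                               sdDenominator = c("n-1", "n")) {
  new("SegmentationParams", capMultiplier = capMultiplier,
      sigmaBackground = sigmaBackground, rollingBallRadius = rollingBallRadius,
      sigmaSmooth = sigmaSmooth, sigmaWatershed = sigmaWatershed,
      cytosolThreshold = cytosolThreshold, noiseMultiplier = noiseMultiplier,
      minArea = minArea, sdDenominator = match.arg(sdDenominator))
}

#' Object-to-object overlap table between two label masks
#'
#' Pixel-overlap counts and per-pair intersection-over-union between every
#' ground-truth object (rows) and predicted object (columns) that intersect.
#'
#' @slot overlap numeric matrix of pixel-overlap counts (Kt x Kp).
#' @slot iou numeric matrix of per-pair IoU values in `[0, 1]`.
#' @slot truthAreas integer vector of ground-truth object areas (px).
#' @slot predAreas integer vector of predicted object areas (px).
#' @export
setClass("MatchTable",
  representation(overlap = "matrix", iou = "matrix",
                 truthAreas = "integer", predAreas = "integer")
)

setValidity("MatchTable", function(object) {
  if (!identical(dim(object@overlap), dim(object@iou)))
    return("overlap and iou must have identical dimensions")
  if (length(object@truthAreas) != nrow(object@overlap) ||
      length(object@predAreas) != ncol(object@overlap))
    return("area vectors must match table dimensions")
  if (any(object@iou < 0 | object@iou > 1)) return("IoU must lie in [0, 1]")
  if (nrow(object@overlap) > 0 &&
      any(rowSums(object@overlap) > object@truthAreas + 1e-9))
    return("row sums cannot exceed ground-truth object areas")
  TRUE
})

#' Segmentation evaluation report
#'
#' Category counts and derived metrics of the human-comparison evaluation
#' protocol, computed against a ground-truth label mask.
#'
#' @slot manuallyCounted number of ground-truth cells.
#' @slot correctlySegmented cells with > 90 percent of their area inside their
#'   (mutually best) detection frame.
#' @slot missed cells no detection overlaps.
#' @slot underSegmented cells that are part of a multi-cell detection (or
#'   whose frame is much larger than the cell).
#' @slot overSegmented cells split across detections or only partially
#'   detected.
#' @slot debris detections overlapping no ground-truth cell.
#' @slot truePositives,falsePositives,falseNegatives detection-level counts.
#' @slot accuracy `100 * TP / (TP + FP + FN)`.
#' @slot sensitivity `100 * TP / (TP + FN)`.
#' @slot percentCorrect `100 * correctlySegmented / manuallyCounted`.
#' @slot meanIoU mean best-match IoU over ground-truth cells.
#' @slot gtCategory per-ground-truth-cell category (diagnostic).
#' @export
setClass("EvalReport",
  representation(manuallyCounted = "integer", correctlySegmented = "integer",
                 missed = "integer", underSegmented = "integer",
                 overSegmented = "integer", debris = "integer",
                 truePositives = "integer", falsePositives = "integer",
                 falseNegatives = "integer", accuracy = "numeric",
                 sensitivity = "numeric", percentCorrect = "numeric",
                 meanIoU = "numeric", gtCategory = "character")
)

setValidity("EvalReport", function(object) {
  cnt <- c(object@manuallyCounted, object@correctlySegmented, object@missed,
           object@underSegmented, object@overSegmented, object@debris,
           object@truePositives, object@falsePositives, object@falseNegatives)
  if (any(cnt < 0L)) return("counts must be non-negative")
  if (object@truePositives > object@manuallyCounted)
    return("true positives cannot exceed manually counted cells")
  pct <- c(object@accuracy, object@sensitivity, object@percentCorrect)
  if (any(!is.nan(pct) & (pct < 0 | pct > 100)))
    return("percentages must lie in [0, 100]")
  if (!is.nan(object@meanIoU) && (object@meanIoU < 0 || object@meanIoU > 1))
    return("meanIoU must lie in [0, 1]")
  TRUE
})

#' Parameters of the synthetic confocal scene generator
#'
#' Describes one simulated field of adherent cells stained with a leaky
#' nuclear dye: bright compact nuclei, a weak cytosolic plateau, a smooth
#' illumination gradient that is static across Z, and per-slice shot-like
#' noise. See [generateScene()] for the rendering model.
#'
#' @slot nCells number of cells to place.
#' @slot fieldSize integer c(rows, cols) of the field in pixels.
#' @slot pixelSize lateral pixel size, um.
#' @slot sliceSpacing axial slice spacing, um.
#' @slot nSlices number of Z slices.
#' @slot nucleusRadius c(mean, sd) of nuclear radius, um.
#' @slot cellRadius c(mean, sd) of cell radius, um.
#' @slot nuclearIntensity peak nuclear signal, gray levels.
#' @slot cytosolIntensity cytosolic plateau, gray levels (well below nuclear).
#' @slot backgroundLevel constant background offset, gray levels.
#' @slot backgroundGradientAmplitude amplitude of the smooth illumination
#'   gradient, gray levels.
#' @slot noiseSd base standard deviation of the per-slice noise, gray levels.
#' @slot clumping fraction in `[0, 1]` of cells placed adjacent to an
#'   existing cell.
#' @slot bitDepth 8 or 16.
#' @slot seed integer RNG seed; the scene is a pure function of its params.
#' @export
setClass("SceneParams",
  representation(nCells = "integer", fieldSize = "integer",
                 pixelSize = "numeric", sliceSpacing = "numeric",
                 nSlices = "integer", nucleusRadius = "numeric",
                 cellRadius = "numeric", nuclearIntensity = "numeric",
                 cytosolIntensity = "numeric", backgroundLevel = "numeric",
                 backgroundGradientAmplitude = "numeric", noiseSd = "numeric",
                 clumping = "numeric", bitDepth = "integer", seed = "integer")
)

setValidity("SceneParams", function(object) {
  if (object@nCells < 0L) return("nCells must be >= 0")
  if (length(object@fieldSize) != 2L || any(object@fieldSize < 16L))
    return("fieldSize must be c(rows, cols), each >= 16")
  if (object@pixelSize <= 0 || object@sliceSpacing <= 0)
    return("pixelSize and sliceSpacing must be positive")
  if (object@nSlices < 2L) return("need at least 2 slices for an SD projection")
  if (any(object@nucleusRadius <= 0) || any(object@cellRadius <= 0) ||
      object@nucleusRadius[1] >= object@cellRadius[1])
    return("radii must be positive with nucleus mean < cell mean")
  if (object@cytosolIntensity >= object@nuclearIntensity)
    return("cytosolIntensity must be below nuclearIntensity")
  if (object@clumping < 0 || object@clumping > 1)
    return("clumping must lie in [0, 1]")
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  TRUE
})

#' @param nCells,fieldSize,pixelSize,sliceSpacing,nSlices see slots.
#' @param nucleusRadius,cellRadius,nuclearIntensity,cytosolIntensity see slots.
#' @param backgroundLevel,backgroundGradientAmplitude,noiseSd see slots.
#' @param clumping,bitDepth,seed see slots.
#' @rdname SceneParams-class
#' @export
sceneParams <- function(nCells = 10, fieldSize = c(512, 512), pixelSize = 0.6,
                        sliceSpacing = 1.51, nSlices = 7,
                        nucleusRadius = c(6, 0.7), cellRadius = c(15, 2),
                        nuclearIntensity = 220, cytosolIntensity = 20,
                        backgroundLevel = 8, backgroundGradientAmplitude = 15,
                        noiseSd = 1.2, clumping = 0, bitDepth = 8L,
                        seed = 1L) {
  new("SceneParams", nCells = as.integer(nCells),
      fieldSize = as.integer(fieldSize), pixelSize = pixelSize,
      sliceSpacing = sliceSpacing, nSlices = as.integer(nSlices),
      nucleusRadius = nucleusRadius, cellRadius = cellRadius,
      nuclearIntensity = nuclearIntensity,
      cytosolIntensity = cytosolIntensity, backgroundLevel = backgroundLevel,
      backgroundGradientAmplitude = backgroundGradientAmplitude,
      noiseSd = noiseSd, clumping = clumping, bitDepth = as.integer(bitDepth),
      seed = as.integer(seed))
}
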