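#' Standard-deviation Z-projection
#'
#' Collapses a Z-stack to a 2-D image in which every pixel holds the standard
#' deviation of the intensities along the axial direction. Regions whose
#' intensity varies through the stack -- both bright nuclei and the weak
#' cytosolic halo of a leaky nuclear dye -- light up, while static structure
#' such as uneven illumination projects to (nearly) zero. The calibration of
#' the stack is carried over.
#'
#' @param stack a [ZStack-class].
#' @param denominator `"n-1"` for the sample standard deviation (default,
#'   matching the common Z-projector convention) or `"n"` for the population
#'   version. Downstream thresholds are ratio-based, so the choice has little
#'   practical effect.
#' @return a [ProjectedImage-class]; all zeros for a single-slice stack.
#' @examples
#' v <- array(c(0, 2), dim = c(1, 1, 2))
#' pixels(sdProjection(ZStack(v)))   # sqrt(2)
#' @export
sdProjection <- function(stack, denominator = c("n-1", "n")) {
  stopifnot(is(stack, "ZStack"))
  denominator <- match.arg(denominator)
  v <- voxels(stack)
  d <- dim(v)
  if (d[3] < 1L) stop("stack has no slices")
  flat <- matrix(v, nrow = d[1] * d[2], ncol = d[3])
  n <- d[3]
  if (n == 1L) {
    px <- matrix(0, d[1], d[2])
  } else {
    mu <- rowMeans(flat)
    ss <- rowSums((flat - mu)^2)
    den <- if (denominator == "n-1") n - 1L else n
    px <- matrix(sqrt(ss / den), d[1], d[2])
  }
  ProjectedImage(px, calibration(stack))
}

#' Convert physical lengths and areas to pixel units
#'
#' All pipeline parameters are stated in micrometres; these helpers convert
#' them onto the image grid. No rounding is performed -- callers round
#' according to their own convention.
#'
#' @param lengthUm length in micrometres.
#' @param areaUm2 area in square micrometres.
#' @param cal a [Calibration-class].
#' @return `umToPx`: length in pixels; `um2ToPx2`: area in square pixels;
#'   `pxToUm` / `px2ToUm2`: the inverse conversions.
#' @examples
#' umToPx(100, Calibration(pixelSizeXY = 0.6))    # 166.67 px
#' um2ToPx2(200, Calibration(pixelSizeXY = 0.6))  # 555.56 px^2
#' @export
umToPx <- function(lengthUm, cal) {
  stopifnot(is(cal, "Calibration"))
  validObject(cal)
  lengthUm / cal@pixelSizeXY
}

#' @rdname umToPx
#' @export
um2ToPx2 <- function(areaUm2, cal) {
  stopifnot(is(cal, "Calibration"))
  validObject(cal)
  areaUm2 / cal@pixelSizeXY^2
}

#' @param lengthPx length in pixels.
#' @rdname umToPx
#' @export
pxToUm <- function(lengthPx, cal) {
  stopifnot(is(cal, "Calibration"))
  lengthPx * cal@pixelSizeXY
}

#' @param areaPx2 area in square pixels.
#' @rdname umToPx
#' @export
px2ToUm2 <- function(areaPx2, cal) {
  stopifnot(is(cal, "Calibration"))
  areaPx2 * cal@pixelSizeXY^2
}
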