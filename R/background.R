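#' Cap high intensities at a multiple of the global mean
#'
#' First step of the background-image construction: intensities above
#' `capMultiplier` times the global mean gray value (zeros included) are
#' clipped to that cap, so that bright nuclei do not dominate the heavily
#' blurred background estimate while the weak cytosolic signal passes
#' through. An all-zero image yields a cap of 0 and is returned unchanged.
#'
#' @param img a [ProjectedImage-class].
#' @param capMultiplier positive multiplier of the global mean (default 3).
#' @return a [ProjectedImage-class] with values clipped at the cap.
#' @export
capIntensities <- function(img, capMultiplier = 3) {
  stopifnot(is(img, "ProjectedImage"), capMultiplier > 0)
  px <- pixels(img)
  cap <- capMultiplier * mean(px)
  ProjectedImage(pmin(px, cap), calibration(img))
}

#' Gaussian blur with a physically calibrated sigma
#'
#' Isotropic Gaussian filter whose sigma is given in micrometres and
#' converted through the image calibration (`sigmaPx = sigmaUm / pixelSize`).
#' Boundaries are handled by edge replication and the kernel is normalised,
#' so constant images are preserved exactly and the operator is exactly
#' linear (scaling the input by `s` scales the output by `s`).
#'
#' Very large sigmas (> 24 px) are computed on a block-mean-reduced pyramid
#' level and restored by bilinear interpolation; every step of that path is
#' itself linear and constant-preserving, and the added block variance
#' (`(s^2 - 1) / 12` px^2) is negligible against such sigmas, so the result
#' matches the direct convolution to a fraction of a percent at a fraction
#' of the cost.
#'
#' @param img a [ProjectedImage-class].
#' @param sigmaUm Gaussian sigma in micrometres (> 0).
#' @return the blurred [ProjectedImage-class].
#' @export
gaussianBlurPhysical <- function(img, sigmaUm) {
  stopifnot(is(img, "ProjectedImage"))
  if (!is.finite(sigmaUm) || sigmaUm <= 0) stop("sigmaUm must be positive")
  sigmaPx <- umToPx(sigmaUm, calibration(img))
  px <- pixels(img)
  if (sigmaPx > 24) {
    s <- max(1L, as.integer(floor(sigmaPx / 12)))
    small <- block_mean_cpp(px, s)
    blurred <- gaussian_blur_cpp(small, sigmaPx / s)
    out <- bilinear_upscale_cpp(blurred, nrow(px), ncol(px), s)
  } else {
    out <- gaussian_blur_cpp(px, sigmaPx)
  }
  ProjectedImage(out, calibration(img))
}

# Offsets and heights of a ball structuring function of radius rPx (pixels;
# intensity units are treated 1:1 with pixels, the ImageJ convention).
.ballElement <- function(rPx) {
  ri <- floor(rPx)
  dx <- rep(-ri:ri, times = 2 * ri + 1)
  dy <- rep(-ri:ri, each = 2 * ri + 1)
  keep <- dx^2 + dy^2 <= rPx^2
  list(dr = as.integer(dy[keep]), dc = as.integer(dx[keep]),
       h = sqrt(rPx^2 - dx[keep]^2 - dy[keep]^2))
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background by rolling a ball of the given physical
#' radius beneath the intensity surface -- a grayscale opening with a ball
#' structuring function -- and subtracts it. Structures broader and smoother
#' than the ball (uneven illumination, slow ramps) are removed; features
#' smaller than the ball (cells, nuclei) are preserved. With the radius set
#' larger than a cell radius, the cytosolic signal is left unaffected.
#'
#' For large radii the image is first reduced by block-minimum downsampling,
#' the ball is rolled on the reduced grid, and the background is restored by
#' bilinear interpolation (the classical acceleration of the algorithm);
#' the restored background is clipped to the image so the result is always
#' non-negative.
#'
#' @param img a [ProjectedImage-class].
#' @param radiusUm ball radius in micrometres; must convert to at least 1 px.
#' @return a [ProjectedImage-class] of `img` minus its estimated background,
#'   non-negative everywhere.
#' @export
rollingBallSubtract <- function(img, radiusUm) {
  stopifnot(is(img, "ProjectedImage"))
  if (!is.finite(radiusUm) || radiusUm <= 0) stop("radiusUm must be positive")
  rPx <- umToPx(radiusUm, calibration(img))
  if (rPx < 1) stop("rolling-ball radius is below 1 px; the ball degenerates")
  px <- pixels(img)
  shrink <- max(1L, as.integer(floor(rPx / 16)))
  if (shrink > 1L) {
    small <- block_min_cpp(px, shrink)
    se <- .ballElement(rPx / shrink)
    bgS <- gray_morph_cpp(gray_morph_cpp(small, se$dr, se$dc, se$h, TRUE),
                          se$dr, se$dc, se$h, FALSE)
    bg <- bilinear_upscale_cpp(bgS, nrow(px), ncol(px), shrink)
    bg <- pmin(bg, px)
  } else {
    se <- .ballElement(rPx)
    bg <- gray_morph_cpp(gray_morph_cpp(px, se$dr, se$dc, se$h, TRUE),
                         se$dr, se$dc, se$h, FALSE)
    bg <- pmin(bg, px)   # opening is anti-extensive; guard numerics only
  }
  ProjectedImage(px - bg, calibration(img))
}

#' Construct the background image (capped + heavily blurred copy)
#'
#' The subtraction mask of the pipeline: the projected image is capped at
#' `capMultiplier` times its global mean and blurred with the large
#' background sigma, producing a smooth background estimate that still
#' carries the broad cytosolic component under each cell.
#'
#' @param img the raw SD projection, a [ProjectedImage-class].
#' @param params a [SegmentationParams-class].
#' @return the background [ProjectedImage-class].
#' @export
buildBackgroundImage <- function(img, params = segmentationParams()) {
  stopifnot(is(params, "SegmentationParams"))
  gaussianBlurPhysical(capIntensities(img, params@capMultiplier),
                       params@sigmaBackground)
}

#' Double background subtraction
#'
#' The full flattening step: the raw projection is first flattened with the
#' rolling ball and lightly smoothed, then the capped-and-blurred background
#' image is subtracted from it. Negative results are clamped to zero so the
#' downstream gray-value threshold is well defined. What remains is an
#' almost flat background containing only nuclear and cytosolic signal.
#'
#' @param img the raw SD projection, a [ProjectedImage-class].
#' @param params a [SegmentationParams-class].
#' @return a non-negative [ProjectedImage-class].
#' @export
subtractBackground <- function(img, params = segmentationParams()) {
  stopifnot(is(img, "ProjectedImage"), is(params, "SegmentationParams"))
  flattened <- gaussianBlurPhysical(
    rollingBallSubtract(img, params@rollingBallRadius), params@sigmaSmooth)
  bg <- buildBackgroundImage(img, params)
  out <- pixels(flattened) - pixels(bg)
  out[out < 0] <- 0
  ProjectedImage(out, calibration(img))
}
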