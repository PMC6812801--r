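#' CENTER control predictor
#'
#' Places the point of interest at the centre pixel of the image regardless
#' of image contents. Even dimensions are resolved by floor, consistent with
#' 0-based indexing: an (r, c) image yields (floor(r/2), floor(c/2)).
#'
#' @param imageShape integer(2), (rows, cols).
#' @return Integer(2), 0-based (row, col).
#' @examples
#' centerPredictor(c(200, 300)) # (100, 150)
#' @export
centerPredictor <- function(imageShape) {
  imageShape <- as.integer(imageShape)
  if (length(imageShape) != 2L || any(is.na(imageShape)) ||
    any(imageShape < 1L)) {
    stop("imageShape must be two positive integers")
  }
  c(row = imageShape[1] %/% 2L, col = imageShape[2] %/% 2L)
}

#' Uniform random point predictor
#'
#' A null reference: points uniform over all pixels, reproducible under a
#' seed (drawn on a private RNG stream; the caller's RNG state is left
#' untouched).
#'
#' @param imageShape integer(2), (rows, cols).
#' @param n number of points.
#' @param seed integer seed.
#' @return An n x 2 matrix of 0-based (row, col) pixel points.
#' @export
uniformRandomPredictor <- function(imageShape, n = 1L, seed) {
  imageShape <- as.integer(imageShape)
  stopifnot(length(imageShape) == 2L, all(imageShape >= 1L), n >= 1L)
  withSeed(seed, {
    cbind(
      row = sample.int(imageShape[1], n, replace = TRUE) - 1L,
      col = sample.int(imageShape[2], n, replace = TRUE) - 1L
    )
  })
}

#' Local-contrast saliency baseline
#'
#' A minimal conspicuity field: the absolute difference between each pixel's
#' intensity and its local surround mean, the surround taken as a Gaussian
#' neighbourhood of scale \code{blurScale} pixels. It serves as a simple
#' stand-in conspicuity computation so the evaluation pipeline runs
#' end-to-end without any third-party saliency model; it makes no claim of
#' emulating any published algorithm.
#'
#' @param image numeric matrix in [0, 1] (or RGB array, collapsed by
#'   unweighted channel mean).
#' @param blurScale Gaussian sigma of the surround, in pixels.
#' @return Nonnegative numeric matrix of the image shape.
#' @export
contrastBaseline <- function(image, blurScale = 8) {
  if (length(blurScale) != 1L || !is.finite(blurScale) || blurScale <= 0) {
    stop("blurScale must be a single positive number")
  }
  img <- toGray(image)
  stopifnot(is.matrix(img), all(is.finite(img)))
  # cap the Gaussian brush at the image size (odd), or gblur cannot filter
  radius <- 2L * as.integer(ceiling(3 * blurScale)) + 1L
  rmax <- min(dim(img))
  if (rmax %% 2L == 0L) rmax <- rmax - 1L
  surround <- EBImage::gblur(img, sigma = blurScale, radius = min(radius, rmax))
  abs(img - surround)
}
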