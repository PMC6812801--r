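# pixels per physical centimetre of screen, from diagonal + resolution
pxPerCm <- function(geometry) {
  diagPx <- sqrt(geometry@resWidthPx^2 + geometry@resHeightPx^2)
  diagPx / geometry@diagonalInch / 2.54
}

#' @rdname pxPerDegree
#' @export
setMethod("pxPerDegree", "ViewingGeometry", function(geometry) {
  validObject(geometry)
  pxPerCm(geometry) * geometry@distanceCm * tan(pi / 180)
})

#' @rdname degreesToPixels
#' @export
setMethod("degreesToPixels", "ViewingGeometry", function(geometry, degrees) {
  validObject(geometry)
  stopifnot(is.numeric(degrees), all(is.finite(degrees)), all(degrees >= 0),
            all(degrees < 90))
  pxPerCm(geometry) * geometry@distanceCm * tan(degrees * pi / 180)
})

#' Binary parafovea disc mask
#'
#' Rasterizes the parafovea disc on an image grid: pixel (i, j) (0-based,
#' origin top-left) is foreground iff the Euclidean distance from its centre
#' to the disc centre is at most the pixel radius (inclusive), so a radius
#' of zero with the centre on a pixel selects exactly that pixel.
#'
#' @param imageShape integer(2), (rows, cols) of the image.
#' @param center disc centre, 0-based (row, col); may be fractional.
#' @param radiusPx disc radius in pixels, or a [ParafoveaSpec-class] in
#'   which case its centre and radius are used and \code{center} is ignored.
#' @return Logical matrix of dim \code{imageShape}; \code{TRUE} inside the
#'   disc.
#' @examples
#' spec <- ParafoveaSpec(center = c(99.5, 149.5))
#' disc <- parafoveaMask(c(200, 300), spec)
#' sum(disc) / (pi * radiusPx(spec)^2) # ~1
#' @export
parafoveaMask <- function(imageShape, center, radiusPx = NULL) {
  if (is(center, "ParafoveaSpec")) {
    radiusPx <- center@radiusPx
    center <- center@center
  }
  imageShape <- as.integer(imageShape)
  if (length(imageShape) != 2L || any(!is.finite(imageShape)) ||
    any(imageShape < 1L)) {
    stop("imageShape must be two positive integers")
  }
  stopifnot(
    length(center) == 2L, all(is.finite(center)),
    length(radiusPx) == 1L, is.finite(radiusPx), radiusPx >= 0
  )
  rows <- seq_len(imageShape[1]) - 1
  cols <- seq_len(imageShape[2]) - 1
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, "+")
  d2 <= radiusPx^2
}

#' Is a point inside the parafovea disc?
#'
#' Membership by Euclidean distance to the disc centre (inclusive), the same
#' rule [parafoveaMask()] uses to rasterize, so a pixel point is inside the
#' disc exactly when the rasterized mask is TRUE at it.
#'
#' @param points numeric(2) or an n x 2 matrix of 0-based (row, col) points.
#' @param spec a [ParafoveaSpec-class].
#' @return Logical vector.
#' @export
inParafovea <- function(points, spec) {
  stopifnot(is(spec, "ParafoveaSpec"))
  p <- asPointMatrix(points)
  sqrt((p[, 1] - spec@center[1])^2 + (p[, 2] - spec@center[2])^2) <=
    spec@radiusPx
}

# coerce a point or point matrix to an n x 2 numeric matrix (0-based row, col)
asPointMatrix <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 2L)
    points <- matrix(as.numeric(points), ncol = 2)
  }
  p <- as.matrix(points)
  stopifnot(ncol(p) == 2L, all(is.finite(p)))
  storage.mode(p) <- "double"
  unname(p)
}

#' Default fixation point of an image
#'
#' Observers in the emulated experiments fixate the image centre; for pixel
#' geometry the centre of an (r, c) image is ((r-1)/2, (c-1)/2) in 0-based
#' coordinates (fractional for even dimensions).
#'
#' @param imageShape integer(2), (rows, cols).
#' @return numeric(2), 0-based (row, col).
#' @export
imageCenter <- function(imageShape) {
  stopifnot(length(imageShape) == 2L, all(imageShape >= 1))
  (as.numeric(imageShape) - 1) / 2
}
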