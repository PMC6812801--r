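#' Centre-bias summary of target masks
#'
#' Summarizes where targets sit relative to the fixation point: the mask
#' centroids, their mean, the fraction of centroids inside the parafovea
#' disc, a pixelwise density (the sum of the overlaid masks — brighter
#' where more masks overlap), and the distance of the mean centroid from
#' the fixation centre in pixels (and degrees when a geometry is given).
#'
#' @param masksList list of logical target masks, all of one shape.
#' @param spec a [ParafoveaSpec-class]; defaults to the 2.5-degree disc at
#'   the image centre of the masks' shape.
#' @param geometry optional [ViewingGeometry-class] for the degree-valued
#'   bias scalar.
#' @return List of class \code{CentroidSummary}: \code{points} (n x 2
#'   centroid matrix), \code{meanCentroid}, \code{fractionInParafovea},
#'   \code{density}, \code{centerOffsetPx}, \code{centerOffsetDeg}, and
#'   \code{n}.
#' @export
centroidScatter <- function(masksList, spec = NULL, geometry = NULL) {
  stopifnot(is.list(masksList), length(masksList) >= 1L)
  shape <- dim(masksList[[1]])
  pts <- t(vapply(masksList, function(m) {
    stopifnot(identical(dim(m), shape))
    maskStats(m)$centroid
  }, numeric(2)))
  density <- Reduce(`+`, lapply(masksList, function(m) m * 1L))
  summarizeScatter(pts, shape, spec, geometry, density = density)
}

#' Centre-bias summary of predicted points
#'
#' The same summaries as [centroidScatter()], computed over predicted points
#' instead of mask centroids; the density is the pixel accumulation array of
#' the points. When \code{targetPresent} is given, summaries are returned
#' separately for target-present and target-absent records, since predictor
#' bias on target-absent images is what exposes built-in spatial priors.
#'
#' @param points n x 2 matrix of 0-based (row, col) points.
#' @param imageShape integer(2).
#' @param spec,geometry as in [centroidScatter()].
#' @param targetPresent optional logical vector along \code{points}.
#' @return A \code{CentroidSummary}, or a list with elements
#'   \code{targetPresent} and \code{targetAbsent} of that class.
#' @export
predictionScatter <- function(points, imageShape, spec = NULL,
                              geometry = NULL, targetPresent = NULL) {
  pts <- asPointMatrix(points)
  imageShape <- as.integer(imageShape)
  if (any(pts[, 1] < 0 | pts[, 1] > imageShape[1] - 1 |
    pts[, 2] < 0 | pts[, 2] > imageShape[2] - 1)) {
    stop("points out of image bounds")
  }
  if (!is.null(targetPresent)) {
    stopifnot(length(targetPresent) == nrow(pts))
    return(list(
      targetPresent = predictionScatter(
        pts[targetPresent, , drop = FALSE], imageShape, spec, geometry
      ),
      targetAbsent = predictionScatter(
        pts[!targetPresent, , drop = FALSE], imageShape, spec, geometry
      )
    ))
  }
  density <- matrix(0L, imageShape[1], imageShape[2])
  if (nrow(pts) > 0L) {
    idx <- round(pts) + 1L
    tab <- table(factor(
      (idx[, 2] - 1L) * imageShape[1] + idx[, 1],
      levels = seq_len(prod(imageShape))
    ))
    density[] <- as.integer(tab)
  }
  summarizeScatter(pts, imageShape, spec, geometry, density = density)
}

summarizeScatter <- function(pts, shape, spec, geometry, density) {
  if (is.null(spec)) {
    spec <- ParafoveaSpec(center = imageCenter(shape))
  }
  n <- nrow(pts)
  meanCentroid <- if (n > 0L) colMeans(pts) else c(NA_real_, NA_real_)
  offPx <- if (n > 0L) {
    sqrt(sum((meanCentroid - spec@center)^2))
  } else {
    NA_real_
  }
  offDeg <- if (!is.null(geometry) && is.finite(offPx)) {
    offPx / pxPerDegree(geometry)
  } else {
    NA_real_
  }
  structure(
    list(
      points = pts,
      meanCentroid = meanCentroid,
      fractionInParafovea = if (n > 0L) mean(inParafovea(pts, spec)) else NA_real_,
      density = density,
      centerOffsetPx = offPx,
      centerOffsetDeg = offDeg,
      n = n
    ),
    class = "CentroidSummary"
  )
}

#' @export
print.CentroidSummary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "CentroidSummary: n = %d, mean (%.2f, %.2f), ",
      "%.1f%% in parafovea, centre offset %.2f px\n"
    ),
    x$n, x$meanCentroid[1], x$meanCentroid[2],
    100 * x$fractionInParafovea, x$centerOffsetPx
  ))
  invisible(x)
}
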