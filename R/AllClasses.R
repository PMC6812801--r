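#' @import methods
NULL

#' Viewing geometry of the display
#'
#' Physical display and observer parameters that fix the conversion between
#' visual angle and screen pixels: observer distance, monitor diagonal and
#' native resolution. The default values describe a common psychophysics
#' setup (57 cm viewing distance, 23-inch 1920x1080 monitor); at 57 cm one
#' centimetre on the screen subtends almost exactly one degree.
#'
#' @slot distanceCm observer-to-screen distance in centimetres.
#' @slot diagonalInch monitor diagonal in inches.
#' @slot resWidthPx,resHeightPx native screen resolution in pixels.
#'
#' @seealso [pxPerDegree()], [degreesToPixels()], [ParafoveaSpec]
#' @export
setClass("ViewingGeometry",
  representation(
    distanceCm = "numeric",
    diagonalInch = "numeric",
    resWidthPx = "numeric",
    resHeightPx = "numeric"
  )
)

setValidity("ViewingGeometry", function(object) {
  v <- c(
    distanceCm = object@distanceCm, diagonalInch = object@diagonalInch,
    resWidthPx = object@resWidthPx, resHeightPx = object@resHeightPx
  )
  if (length(v) != 4L || any(!is.finite(v))) {
    return("all geometry fields must be finite scalars")
  }
  if (any(v <= 0)) {
    return(paste0(
      "geometry fields must be strictly positive; offending: ",
      paste(names(v)[v <= 0], collapse = ", ")
    ))
  }
  TRUE
})

#' Construct a ViewingGeometry
#'
#' @param distanceCm observer distance in cm.
#' @param diagonalInch monitor diagonal in inches.
#' @param resWidthPx,resHeightPx screen resolution in pixels.
#' @return A [ViewingGeometry-class] object.
#' @examples
#' geom <- ViewingGeometry()
#' pxPerDegree(geom)
#' @export
ViewingGeometry <- function(distanceCm = 57, diagonalInch = 23,
                            resWidthPx = 1920, resHeightPx = 1080) {
  new("ViewingGeometry",
    distanceCm = as.numeric(distanceCm),
    diagonalInch = as.numeric(diagonalInch),
    resWidthPx = as.numeric(resWidthPx),
    resHeightPx = as.numeric(resHeightPx)
  )
}

#' Parafovea disc specification
#'
#' The parafovea is modelled as a hard disc of fixed visual-angle radius
#' (default 2.5 degrees) centred at the observer's fixation point, expressed
#' in 0-based (row, col) pixel coordinates of the stimulus image. The pixel
#' radius is derived from the visual-angle radius through a
#' [ViewingGeometry-class] and stored alongside it.
#'
#' @slot center numeric(2), fixation point as 0-based (row, col).
#' @slot radiusDeg disc radius in degrees of visual angle.
#' @slot radiusPx disc radius in pixels, derived from the geometry.
#'
#' @seealso [parafoveaMask()], [degreesToPixels()]
#' @export
setClass("ParafoveaSpec",
  representation(
    center = "numeric",
    radiusDeg = "numeric",
    radiusPx = "numeric"
  )
)

setValidity("ParafoveaSpec", function(object) {
  if (length(object@center) != 2L || any(!is.finite(object@center))) {
    return("center must be a finite (row, col) pair")
  }
  if (length(object@radiusDeg) != 1L || !is.finite(object@radiusDeg) ||
    object@radiusDeg <= 0) {
    return("radiusDeg must be a single positive number")
  }
  if (length(object@radiusPx) != 1L || !is.finite(object@radiusPx) ||
    object@radiusPx < 0) {
    return("radiusPx must be a single nonnegative number")
  }
  TRUE
})

#' Construct a ParafoveaSpec
#'
#' @param center fixation point, 0-based (row, col). Typically the image
#'   centre, since observers in rapid-categorization experiments fixate
#'   the centre of the stimulus.
#' @param radiusDeg disc radius in degrees of visual angle.
#' @param geometry a [ViewingGeometry-class] used to derive the pixel radius.
#' @param radiusPx optional explicit pixel radius; when supplied it overrides
#'   the geometric conversion (useful for sensitivity analyses).
#' @return A [ParafoveaSpec-class] object.
#' @examples
#' spec <- ParafoveaSpec(center = c(127.5, 191.5))
#' radiusPx(spec)
#' @export
ParafoveaSpec <- function(center, radiusDeg = 2.5,
                          geometry = ViewingGeometry(), radiusPx = NULL) {
  if (is.null(radiusPx)) {
    radiusPx <- degreesToPixels(geometry, radiusDeg)
  }
  new("ParafoveaSpec",
    center = as.numeric(center),
    radiusDeg = as.numeric(radiusDeg),
    radiusPx = as.numeric(radiusPx)
  )
}

#' A set of stimuli with ground-truth target masks
#'
#' Container for a stimulus collection: a manifest (one row per image with
#' its target-present flag and dataset label), the binary ground-truth
#' target masks (GTMs) for target-present images, and optionally the image
#' pixel data. All images in a set share one shape. Masks are logical
#' matrices; \code{TRUE} marks target pixels.
#'
#' @slot manifest data.frame with columns \code{id}, \code{image},
#'   \code{mask}, \code{targetPresent}, \code{dataset}. Path columns may be
#'   \code{NA} for purely synthetic in-memory sets.
#' @slot masks named list of logical matrices, one per target-present id.
#' @slot images named list of numeric matrices in [0, 1] (possibly empty).
#' @slot imageShape integer(2), common (rows, cols) of all images.
#'
#' @seealso [loadManifest()], [generateDataset()]
#' @export
setClass("StimulusSet",
  representation(
    manifest = "data.frame",
    masks = "list",
    images = "list",
    imageShape = "integer"
  )
)

setValidity("StimulusSet", function(object) {
  m <- object@manifest
  need <- c("id", "image", "mask", "targetPresent", "dataset")
  if (!all(need %in% names(m))) {
    return(paste(
      "manifest must have columns:",
      paste(setdiff(need, names(m)), collapse = ", ")
    ))
  }
  if (anyDuplicated(m$id)) {
    return("manifest ids must be unique")
  }
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L)) {
    return("imageShape must be two positive integers")
  }
  present <- m$id[m$targetPresent]
  if (!setequal(names(object@masks), present)) {
    return("masks must be present exactly for the target-present ids")
  }
  for (id in names(object@masks)) {
    mk <- object@masks[[id]]
    if (!is.logical(mk) || !identical(dim(mk), as.integer(object@imageShape))) {
      return(sprintf("mask '%s' is not a logical matrix of the set shape", id))
    }
    if (!any(mk)) {
      return(sprintf("mask '%s' is empty but marked target-present", id))
    }
  }
  for (id in names(object@images)) {
    im <- object@images[[id]]
    if (!identical(dim(im)[1:2], as.integer(object@imageShape))) {
      return(sprintf("image '%s' does not match the set shape", id))
    }
  }
  TRUE
})

#' Configuration of the synthetic stimulus generator
#'
#' Parameters controlling a generated stimulus set: counts, image shape,
#' centre bias of the target centroids (an isotropic Gaussian in degrees of
#' visual angle, truncated so the whole target fits in-frame), the target
#' area range, the accuracy of the synthetic point predictor, and the
#' psychometric link tying response correctness to target-parafovea overlap.
#'
#' @slot nImages total number of images.
#' @slot nTargetPresent number of images containing a target.
#' @slot imageShape integer(2), (rows, cols).
#' @slot centroidSpreadDeg standard deviation of the target-centroid
#'   distribution about the image centre, in degrees.
#' @slot targetAreaPxRange numeric(2), (min, max) target area in pixels.
#' @slot predictorAccuracy probability q that the synthetic predictor lands
#'   inside the target mask (otherwise it falls uniformly on the image).
#' @slot psychMidpoint,psychSlope logistic psychometric parameters: the
#'   probability of a correct response is
#'   \code{plogis((overlap - psychMidpoint) * psychSlope)}.
#' @slot seed master seed; per-artifact streams are derived from it.
#' @slot datasetId label written into the manifest.
#' @slot geometry the [ViewingGeometry-class] used for degree-pixel
#'   conversions.
#'
#' @seealso [synthConfig()], [generateDataset()]
#' @export
setClass("SynthConfig",
  representation(
    nImages = "integer",
    nTargetPresent = "integer",
    imageShape = "integer",
    centroidSpreadDeg = "numeric",
    targetAreaPxRange = "numeric",
    predictorAccuracy = "numeric",
    psychMidpoint = "numeric",
    psychSlope = "numeric",
    seed = "integer",
    datasetId = "character",
    geometry = "ViewingGeometry"
  )
)

setValidity("SynthConfig", function(object) {
  if (object@nImages < 1L) {
    return("nImages must be >= 1")
  }
  if (object@nTargetPresent < 0L || object@nTargetPresent > object@nImages) {
    return("nTargetPresent must lie in [0, nImages]")
  }
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L)) {
    return("imageShape must be two integers >= 8")
  }
  if (object@centroidSpreadDeg < 0) {
    return("centroidSpreadDeg must be nonnegative")
  }
  ar <- object@targetAreaPxRange
  if (length(ar) != 2L || any(ar <= 0) || ar[1] > ar[2]) {
    return("targetAreaPxRange must be positive (min, max) with min <= max")
  }
  # largest semi-axis under the maximal aspect jitter must fit in-frame
  aMax <- sqrt(ar[2] * exp(0.5) / pi)
  if (2 * aMax >= min(object@imageShape)) {
    return("target area range allows targets larger than the image")
  }
  q <- object@predictorAccuracy
  if (q < 0 || q > 1) {
    return("predictorAccuracy must lie in [0, 1]")
  }
  if (object@psychSlope < 0) {
    return("psychSlope must be nonnegative")
  }
  TRUE
})

#' Confusion-matrix summary for a yes/no categorization stage
#'
#' Row-normalized confusion rates for a detection task: TP + FN = 1 over
#' target-present trials, TN + FP = 1 over target-absent trials, and
#' accuracy = (TP * nPos + TN * nNeg) / (nPos + nNeg).
#'
#' @slot tp,fn,tn,fp rates in [0, 1].
#' @slot nPos,nNeg trial counts per class.
#' @slot accuracy overall proportion correct.
#'
#' @seealso [confusionSummary()], [idsConfusion()]
#' @export
setClass("ConfusionSummary",
  representation(
    tp = "numeric", fn = "numeric", tn = "numeric", fp = "numeric",
    nPos = "numeric", nNeg = "numeric", accuracy = "numeric"
  )
)

setValidity("ConfusionSummary", function(object) {
  r <- c(object@tp, object@fn, object@tn, object@fp, object@accuracy)
  if (any(!is.finite(r)) || any(r < -1e-9) || any(r > 1 + 1e-9)) {
    return("all rates must lie in [0, 1]")
  }
  if (abs(object@tp + object@fn - 1) > 1e-8) {
    return("tp + fn must equal 1 (row-normalized over target-present)")
  }
  if (abs(object@tn + object@fp - 1) > 1e-8) {
    return("tn + fp must equal 1 (row-normalized over target-absent)")
  }
  if (object@nPos <= 0 || object@nNeg <= 0) {
    return("nPos and nNeg must be positive")
  }
  acc <- (object@tp * object@nPos + object@tn * object@nNeg) /
    (object@nPos + object@nNeg)
  if (abs(acc - object@accuracy) > 1e-8) {
    return("accuracy inconsistent with (TP*nPos + TN*nNeg)/(nPos + nNeg)")
  }
  TRUE
})
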