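#' Accessors
#'
#' Slot accessors for the package's S4 classes.
#'
#' @param object an object of the documented classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("radiusPx", "ParafoveaSpec", function(object) object@radiusPx)

#' @rdname accessors
#' @export
setMethod("radiusDeg", "ParafoveaSpec", function(object) object@radiusDeg)

#' @rdname accessors
#' @export
setMethod("fixationCenter", "ParafoveaSpec", function(object) object@center)

#' @rdname accessors
#' @export
setMethod("manifest", "StimulusSet", function(object) object@manifest)

#' @rdname accessors
#' @export
setMethod("masks", "StimulusSet", function(object) object@masks)

#' @rdname accessors
#' @export
setMethod("images", "StimulusSet", function(object) object@images)

#' @rdname accessors
#' @export
setMethod("imageShape", "StimulusSet", function(object) object@imageShape)

#' @rdname accessors
#' @export
setMethod("accuracy", "ConfusionSummary", function(object) object@accuracy)

#' @rdname accessors
#' @export
setMethod("rates", "ConfusionSummary", function(object) {
  c(tp = object@tp, fn = object@fn, tn = object@tn, fp = object@fp)
})

#' @rdname accessors
#' @param x a \code{StimulusSet}.
#' @export
setMethod("length", "StimulusSet", function(x) nrow(x@manifest))

setMethod("show", "ViewingGeometry", function(object) {
  cat(sprintf(
    "ViewingGeometry: %.4g cm distance, %.4g\" diagonal, %dx%d px\n",
    object@distanceCm, object@diagonalInch,
    as.integer(object@resWidthPx), as.integer(object@resHeightPx)
  ))
  cat(sprintf("  %.3f px per degree\n", pxPerDegree(object)))
})

setMethod("show", "ParafoveaSpec", function(object) {
  cat(sprintf(
    "ParafoveaSpec: r = %.3g deg (%.2f px) at (row %.6g, col %.6g)\n",
    object@radiusDeg, object@radiusPx, object@center[1], object@center[2]
  ))
})

setMethod("show", "StimulusSet", function(object) {
  m <- object@manifest
  cat(sprintf(
    "StimulusSet: %d images (%dx%d), %d target-present\n",
    nrow(m), object@imageShape[1], object@imageShape[2], sum(m$targetPresent)
  ))
  for (ds in unique(m$dataset)) {
    sel <- m$dataset == ds
    cat(sprintf(
      "  %s: %d images, %d with target\n",
      ds, sum(sel), sum(m$targetPresent[sel])
    ))
  }
  if (length(object@images)) {
    cat(sprintf("  pixel data held for %d images\n", length(object@images)))
  }
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig '%s': %d images (%d target-present), %dx%d\n",
    object@datasetId, object@nImages, object@nTargetPresent,
    object@imageShape[1], object@imageShape[2]
  ))
  cat(sprintf(
    "  centroid spread %.3g deg, target area %g-%g px, q = %.3g, seed %d\n",
    object@centroidSpreadDeg, object@targetAreaPxRange[1],
    object@targetAreaPxRange[2], object@predictorAccuracy, object@seed
  ))
})

setMethod("show", "ConfusionSummary", function(object) {
  cat(sprintf(
    paste0(
      "ConfusionSummary: accuracy %.3f ",
      "(TP %.2f FN %.2f TN %.2f FP %.2f; n+ %d, n- %d)\n"
    ),
    object@accuracy, object@tp, object@fn, object@tn, object@fp,
    as.integer(object@nPos), as.integer(object@nNeg)
  ))
})
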