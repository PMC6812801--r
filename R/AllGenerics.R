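#' Pixels per degree of visual angle
#'
#' The number of screen pixels subtended by one degree of visual angle:
#' (pixels per physical cm of screen) times the cm subtended per degree at
#' the viewing distance d, taken as d * tan(1 degree).
#'
#' @param geometry a [ViewingGeometry-class].
#' @return A single number (pixels per degree).
#' @examples
#' pxPerDegree(ViewingGeometry()) # ~37.5 px/deg
#' @export
setGeneric("pxPerDegree", function(geometry) standardGeneric("pxPerDegree"))

#' Convert a visual angle to pixels
#'
#' Uses the exact tangent rule: the extent in cm on the screen of an angle
#' theta at distance d is d * tan(theta), converted to pixels through the
#' screen's pixel pitch. At parafoveal angles (2.5 degrees) this differs
#' from the linear per-degree rule by under 0.1 percent.
#'
#' @param geometry a [ViewingGeometry-class].
#' @param degrees visual angle(s) in degrees.
#' @return Extent in pixels, same length as \code{degrees}.
#' @examples
#' degreesToPixels(ViewingGeometry(), 2.5) # ~93.8 px
#' @export
setGeneric("degreesToPixels", function(geometry, degrees) {
  standardGeneric("degreesToPixels")
})

#' @rdname accessors
#' @export
setGeneric("radiusPx", function(object) standardGeneric("radiusPx"))

#' @rdname accessors
#' @export
setGeneric("radiusDeg", function(object) standardGeneric("radiusDeg"))

#' @rdname accessors
#' @export
setGeneric("fixationCenter", function(object) standardGeneric("fixationCenter"))

#' @rdname accessors
#' @export
setGeneric("manifest", function(object) standardGeneric("manifest"))

#' @rdname accessors
#' @export
setGeneric("masks", function(object) standardGeneric("masks"))

#' @rdname accessors
#' @export
setGeneric("images", function(object) standardGeneric("images"))

#' @rdname accessors
#' @export
setGeneric("imageShape", function(object) standardGeneric("imageShape"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))
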