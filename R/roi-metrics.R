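#' Fraction of the target mask inside the parafovea
#'
#' |GTM intersect parafovea| / |GTM|, by pixel count.
#'
#' @param mask logical ground-truth target mask (nonempty).
#' @param parafovea logical disc mask of the same shape (see
#'   [parafoveaMask()]).
#' @return A fraction in [0, 1].
#' @export
overlapFraction <- function(mask, parafovea) {
  stopifnot(
    is.logical(mask), is.logical(parafovea),
    identical(dim(mask), dim(parafovea))
  )
  a <- sum(mask)
  if (a == 0L) {
    stop("mask is empty: overlap fraction undefined")
  }
  sum(mask & parafovea) / a
}

#' Score one predicted point against a target mask
#'
#' Applies the four region-of-interest hit measures to a predicted point P
#' on a target-present image:
#' \describe{
#'   \item{A}{P falls anywhere within the GTM;}
#'   \item{B}{P falls within the GTM and within the parafovea (point
#'     membership, even by a single pixel);}
#'   \item{threshold t (C: 0.27, D: 0.41)}{B holds and at least a fraction
#'     t of the GTM area lies within the parafovea.}
#' }
#'
#' @param p 0-based (row, col) point.
#' @param mask logical target mask (nonempty).
#' @param parafovea logical disc mask of the same shape.
#' @param thresholds overlap thresholds for the graded measures; the
#'   defaults are the human-accuracy-matched values 0.27 and 0.41, labelled
#'   C and D.
#' @return List of class \code{MetricOutcome}: \code{p},
#'   \code{overlapFraction}, \code{hitA}, \code{hitB} and
#'   \code{hitAtThreshold} (named logical vector over \code{thresholds}).
#' @export
evaluatePoint <- function(p, mask, parafovea, thresholds = c(C = 0.27, D = 0.41)) {
  stopifnot(
    is.logical(mask), is.logical(parafovea),
    identical(dim(mask), dim(parafovea)),
    is.numeric(thresholds), all(thresholds >= 0), all(thresholds <= 1)
  )
  p <- as.numeric(p)
  stopifnot(length(p) == 2L, all(is.finite(p)))
  if (any(p < 0) || p[1] > nrow(mask) - 1L || p[2] > ncol(mask) - 1L) {
    stop(sprintf("point (%g, %g) is outside the image", p[1], p[2]))
  }
  i <- as.integer(round(p)) + 1L
  hitA <- mask[i[1], i[2]]
  hitB <- hitA && parafovea[i[1], i[2]]
  ov <- overlapFraction(mask, parafovea)
  hits <- hitB & (ov >= thresholds)
  if (is.null(names(thresholds))) {
    names(hits) <- format(thresholds)
  }
  structure(
    list(
      p = c(row = p[1], col = p[2]),
      overlapFraction = ov,
      hitA = hitA, hitB = hitB,
      hitAtThreshold = hits
    ),
    class = "MetricOutcome"
  )
}

#' @export
print.MetricOutcome <- function(x, ...) {
  cat(sprintf(
    "MetricOutcome: P=(%g, %g), overlap %.3f, A:%s B:%s %s\n",
    x$p[1], x$p[2], x$overlapFraction,
    x$hitA, x$hitB,
    paste(sprintf("%s:%s", names(x$hitAtThreshold), x$hitAtThreshold),
      collapse = " "
    )
  ))
  invisible(x)
}

#' Score a set of predictions against a stimulus set
#'
#' Evaluates one predicted point per image. Target-absent images carry no
#' ground truth, so their hit and overlap columns are \code{NA}; they do not
#' enter any hit-rate computation but are retained for the ideal-decision
#' and bias analyses.
#'
#' @param set a [StimulusSet-class].
#' @param predictions data.frame with columns \code{id}, \code{pRow},
#'   \code{pCol} (0-based), one row per image of \code{set}.
#' @param spec a [ParafoveaSpec-class]; defaults to the 2.5-degree disc at
#'   the image centre under the default geometry.
#' @param thresholds graded-measure thresholds, as in [evaluatePoint()].
#' @return data.frame with one row per image: \code{id}, \code{dataset},
#'   \code{targetPresent}, \code{pRow}, \code{pCol}, \code{overlapFraction},
#'   \code{hitA}, \code{hitB} and one \code{hit<name>} column per threshold.
#' @export
evaluateDataset <- function(set, predictions, spec = NULL,
                            thresholds = c(C = 0.27, D = 0.41)) {
  stopifnot(is(set, "StimulusSet"))
  need <- c("id", "pRow", "pCol")
  stopifnot(all(need %in% names(predictions)))
  man <- set@manifest
  if (!all(man$id %in% predictions$id)) {
    stop("predictions missing for some manifest ids")
  }
  if (is.null(spec)) {
    spec <- ParafoveaSpec(center = imageCenter(set@imageShape))
  }
  disc <- parafoveaMask(set@imageShape, spec)
  pred <- predictions[match(man$id, predictions$id), ]
  thrNames <- names(thresholds)
  if (is.null(thrNames)) {
    thrNames <- format(thresholds)
  }
  out <- data.frame(
    id = man$id, dataset = man$dataset, targetPresent = man$targetPresent,
    pRow = pred$pRow, pCol = pred$pCol,
    overlapFraction = NA_real_, hitA = NA, hitB = NA,
    stringsAsFactors = FALSE
  )
  for (nm in thrNames) {
    out[[paste0("hit", nm)]] <- NA
  }
  for (i in seq_len(nrow(man))) {
    if (!man$targetPresent[i]) next
    mo <- evaluatePoint(
      c(pred$pRow[i], pred$pCol[i]),
      set@masks[[man$id[i]]], disc, thresholds
    )
    out$overlapFraction[i] <- mo$overlapFraction
    out$hitA[i] <- mo$hitA
    out$hitB[i] <- mo$hitB
    out[i, paste0("hit", thrNames)] <- as.list(mo$hitAtThreshold)
  }
  out
}

# target-present subset, with validation
presentOutcomes <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), "hitA" %in% names(outcomes))
  if ("targetPresent" %in% names(outcomes)) {
    outcomes <- outcomes[outcomes$targetPresent, , drop = FALSE]
  }
  outcomes <- outcomes[!is.na(outcomes$hitA), , drop = FALSE]
  if (nrow(outcomes) == 0L) {
    stop("no target-present outcomes")
  }
  outcomes
}

#' Per-measure hit rates over a dataset
#'
#' 100 x (hits / target-present count), per measure, over the target-present
#' images only; target-absent images contribute to no measure.
#'
#' @param outcomes outcome data.frame from [evaluateDataset()].
#' @return Named numeric vector of percentages, one per \code{hit*} column.
#' @export
datasetHitRates <- function(outcomes) {
  outcomes <- presentOutcomes(outcomes)
  hitCols <- grep("^hit", names(outcomes), value = TRUE)
  vapply(hitCols, function(cl) 100 * mean(outcomes[[cl]]), numeric(1))
}

#' Sensitivity of the hit rate to the overlap threshold
#'
#' For each threshold t in the grid, the percentage of target-present images
#' whose point is a measure-B hit and whose GTM has at least a fraction t of
#' its area inside the parafovea. The value at t = 0 is exactly the
#' measure-B rate, and the curve is non-increasing in t.
#'
#' @param outcomes outcome data.frame from [evaluateDataset()].
#' @param thresholdGrid increasing grid of fractions starting at 0.
#' @return data.frame with columns \code{threshold} and \code{hitRate}
#'   (percent).
#' @export
sensitivityCurve <- function(outcomes, thresholdGrid = seq(0, 1, by = 0.05)) {
  stopifnot(is.numeric(thresholdGrid), length(thresholdGrid) >= 1L)
  if (is.unsorted(thresholdGrid, strictly = TRUE)) {
    stop("thresholdGrid must be strictly increasing")
  }
  if (thresholdGrid[1] != 0) {
    stop("thresholdGrid must include 0 (the measure-B point)")
  }
  outcomes <- presentOutcomes(outcomes)
  rate <- vapply(thresholdGrid, function(t) {
    100 * mean(outcomes$hitB & outcomes$overlapFraction >= t)
  }, numeric(1))
  data.frame(threshold = thresholdGrid, hitRate = rate)
}

#' Calibrate an overlap threshold against human accuracy
#'
#' Inverts the empirical survival function of the target-parafovea overlap
#' distribution: returns the largest threshold t such that at least a
#' fraction \code{humanAccuracy} of the targets have overlap >= t. This is
#' how accuracy-matched thresholds are derived (e.g. 94 percent accuracy on
#' one dataset maps to a 27 percent overlap threshold, 73 percent to 41
#' percent on another); no interpolation is used, so the returned value is
#' always an observed overlap.
#'
#' @param overlaps vector of per-target overlap fractions.
#' @param humanAccuracy fraction in (0, 1].
#' @return The calibrated threshold (one of \code{overlaps}).
#' @examples
#' calibrateThreshold(seq(0.1, 1, by = 0.1), 0.7) # 0.4
#' @export
calibrateThreshold <- function(overlaps, humanAccuracy) {
  stopifnot(
    is.numeric(overlaps), all(is.finite(overlaps)),
    all(overlaps >= 0), all(overlaps <= 1)
  )
  if (length(overlaps) == 0L) {
    stop("no overlaps supplied")
  }
  if (length(humanAccuracy) != 1L || humanAccuracy <= 0 ||
    humanAccuracy > 1) {
    stop("humanAccuracy must lie in (0, 1]")
  }
  sorted <- sort(overlaps, decreasing = TRUE)
  k <- ceiling(humanAccuracy * length(sorted))
  sorted[k]
}
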