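#' Crop an image to its parafoveal content
#'
#' Pixels inside the parafovea disc are kept unchanged; everything outside
#' is set to a uniform fill (a light grey by default), producing the
#' cropped-stimulus condition in which observers see only what falls within
#' the parafovea.
#'
#' @param image numeric matrix or (rows, cols, channels) array in [0, 1].
#' @param parafovea logical disc mask matching the image's first two dims.
#' @param fill fill intensity in [0, 1]; a scalar, or one value per channel
#'   for an array image.
#' @return Image of the input shape.
#' @export
cropToParafovea <- function(image, parafovea, fill = 0.78) {
  stopifnot(is.logical(parafovea), is.matrix(parafovea))
  d <- dim(image)
  if (!identical(d[1:2], dim(parafovea))) {
    stop("parafovea mask shape does not match the image")
  }
  stopifnot(all(fill >= 0), all(fill <= 1))
  out <- image
  if (length(d) == 2L) {
    stopifnot(length(fill) == 1L)
    out[!parafovea] <- fill
  } else {
    if (length(fill) == 1L) {
      fill <- rep(fill, d[3])
    }
    stopifnot(length(fill) == d[3])
    for (k in seq_len(d[3])) {
      ch <- out[, , k]
      ch[!parafovea] <- fill[k]
      out[, , k] <- ch
    }
  }
  out
}

# bin index on (0, 1], right-closed equal-width bins; overlap 0 gets NA
overlapBin <- function(overlap, nBins) {
  idx <- ceiling(overlap * nBins)
  idx[overlap <= 0 | overlap > 1 | !is.finite(overlap)] <- NA_integer_
  as.integer(idx)
}

boxStats <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  list(
    median = q[2], q1 = q[1], q3 = q[3],
    whiskerLow = min(values[inside]), whiskerHigh = max(values[inside]),
    outliers = values[!inside]
  )
}

#' Bin categorization accuracy by target-parafovea overlap
#'
#' Aggregates trial-level correctness into 10 (by default) equal-width,
#' right-closed bins of the overlap fraction on (0, 1]. Within each bin the
#' distribution summarized is the per-subject mean accuracies, and the box
#' statistics follow the usual plotting convention: median, quartiles by
#' linear interpolation, whiskers at the most extreme values within 1.5 IQR
#' of the quartiles, values beyond flagged as outliers.
#'
#' @param trials data.frame with columns \code{subject}, \code{overlap}
#'   (fraction of the target inside the parafovea) and \code{correct}
#'   (logical). A \code{condition} column (\code{"full"} / \code{"cropped"})
#'   is carried through if constant, ignored otherwise.
#' @param nBins number of bins partitioning (0, 1].
#' @return List of class \code{BinnedAccuracy}: \code{stats}, a data.frame
#'   with one row per bin (\code{binLow}, \code{binHigh}, \code{n} subject
#'   values, \code{nTrials}, box statistics, all \code{NA} when the bin is
#'   empty), and \code{outliers}, a list of outlier values per bin.
#' @export
binAccuracyByOverlap <- function(trials, nBins = 10L) {
  if (length(nBins) != 1L || nBins < 1L) {
    stop("nBins must be a positive integer")
  }
  nBins <- as.integer(nBins)
  need <- c("subject", "overlap", "correct")
  stopifnot(is.data.frame(trials), all(need %in% names(trials)))
  stopifnot(all(trials$overlap >= 0 & trials$overlap <= 1, na.rm = TRUE))
  bin <- overlapBin(trials$overlap, nBins)
  if (anyNA(bin)) {
    warning(sum(is.na(bin)), " trial(s) with zero/undefined overlap dropped")
  }
  edges <- seq(0, 1, length.out = nBins + 1)
  out <- data.frame(
    binLow = edges[-(nBins + 1)], binHigh = edges[-1],
    n = 0L, nTrials = 0L,
    median = NA_real_, q1 = NA_real_, q3 = NA_real_,
    whiskerLow = NA_real_, whiskerHigh = NA_real_
  )
  outliers <- vector("list", nBins)
  for (b in seq_len(nBins)) {
    sel <- !is.na(bin) & bin == b
    out$nTrials[b] <- sum(sel)
    if (!any(sel)) next
    acc <- tapply(trials$correct[sel], trials$subject[sel], mean)
    acc <- as.numeric(acc[!is.na(acc)])
    out$n[b] <- length(acc)
    bs <- boxStats(acc)
    out[b, c("median", "q1", "q3", "whiskerLow", "whiskerHigh")] <-
      bs[c("median", "q1", "q3", "whiskerLow", "whiskerHigh")]
    outliers[[b]] <- bs$outliers
  }
  structure(list(stats = out, outliers = outliers), class = "BinnedAccuracy")
}

#' @export
print.BinnedAccuracy <- function(x, ...) {
  cat("BinnedAccuracy over", nrow(x$stats), "overlap bins\n")
  print(x$stats, digits = 3)
  invisible(x)
}

#' Algorithm accuracy as a function of target-parafovea overlap
#'
#' The algorithmic analogue of the human binned analysis: the measure-A hit
#' percentage within equal-width overlap bins on (0, 1], computed over
#' target-present outcomes.
#'
#' @param outcomes outcome data.frame from [evaluateDataset()].
#' @param nBins number of bins.
#' @return data.frame with one row per bin: \code{binLow}, \code{binHigh},
#'   \code{n} and \code{hitRate} (percent, \code{NA} for empty bins).
#' @export
algorithmAccuracyByOverlap <- function(outcomes, nBins = 10L) {
  if (length(nBins) != 1L || nBins < 1L) {
    stop("nBins must be a positive integer")
  }
  nBins <- as.integer(nBins)
  outcomes <- presentOutcomes(outcomes)
  bin <- overlapBin(outcomes$overlapFraction, nBins)
  edges <- seq(0, 1, length.out = nBins + 1)
  out <- data.frame(
    binLow = edges[-(nBins + 1)], binHigh = edges[-1],
    n = 0L, hitRate = NA_real_
  )
  for (b in seq_len(nBins)) {
    sel <- !is.na(bin) & bin == b
    out$n[b] <- sum(sel)
    if (any(sel)) {
      out$hitRate[b] <- 100 * mean(outcomes$hitA[sel])
    }
  }
  out
}
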