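#' Ideal Decision Stage decisions
#'
#' The Ideal Decision Stage (IDS) is a hypothetical perfect recognizer that
#' receives only the saliency-predicted point: on a target-present image it
#' answers "yes" exactly when the gating hit measure holds (default C), and
#' on a target-absent image it always answers "no" — the predicted point
#' never lies on a target, so a false positive is impossible by
#' construction (FP = 0, TN = 1).
#'
#' @param outcomes outcome data.frame from [evaluateDataset()] containing
#'   target-present and target-absent rows.
#' @param measure which hit measure gates a "yes": one of \code{"A"},
#'   \code{"B"} or a graded-threshold name (\code{"C"}, \code{"D"}).
#' @return Logical vector of decisions (\code{TRUE} = "yes"), aligned with
#'   the rows of \code{outcomes}.
#' @export
idsDecide <- function(outcomes, measure = "C") {
  stopifnot(is.data.frame(outcomes), "targetPresent" %in% names(outcomes))
  col <- paste0("hit", match.arg(measure, c("A", "B", "C", "D")))
  if (!col %in% names(outcomes)) {
    stop("unknown measure: no column ", col)
  }
  ifelse(outcomes$targetPresent, outcomes[[col]] %in% TRUE, FALSE)
}

#' Build a ConfusionSummary from rates
#'
#' @param tp true-positive rate over target-present trials.
#' @param tn true-negative rate over target-absent trials.
#' @param nPos,nNeg trial counts per class.
#' @param balanced compute accuracy with equal class weights instead of the
#'   actual counts (the printed-table arithmetic for balanced designs).
#' @return A [ConfusionSummary-class].
#' @examples
#' accuracy(confusionSummary(tp = 0.70, tn = 1.00, nPos = 1, nNeg = 1)) # 0.85
#' @export
confusionSummary <- function(tp, tn, nPos, nNeg, balanced = FALSE) {
  if (nPos <= 0 || nNeg <= 0) {
    stop("both classes need at least one trial")
  }
  if (balanced) {
    # equal pseudo-counts keep the count-weighted accuracy invariant while
    # reproducing the balanced (tp + tn) / 2 arithmetic
    nPos <- nNeg <- mean(c(nPos, nNeg))
  }
  new("ConfusionSummary",
    tp = tp, fn = 1 - tp, tn = tn, fp = 1 - tn,
    nPos = as.numeric(nPos), nNeg = as.numeric(nNeg),
    accuracy = (tp * nPos + tn * nNeg) / (nPos + nNeg)
  )
}

#' Confusion summary from per-trial decisions
#'
#' @param decisions logical vector, \code{TRUE} = "yes".
#' @param labels logical vector, \code{TRUE} = target present.
#' @param balanced as in [confusionSummary()].
#' @return A [ConfusionSummary-class].
#' @export
confusionFromDecisions <- function(decisions, labels, balanced = FALSE) {
  stopifnot(
    is.logical(decisions), is.logical(labels),
    length(decisions) == length(labels), !anyNA(labels)
  )
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L) {
    stop("both classes need at least one trial")
  }
  confusionSummary(
    tp = mean(decisions[labels]),
    tn = mean(!decisions[!labels]),
    nPos = nPos, nNeg = nNeg, balanced = balanced
  )
}

#' Ideal Decision Stage confusion summary for a dataset
#'
#' Applies [idsDecide()] and summarizes: TP equals the gating measure's hit
#' rate over target-present images, and TN = 1, FP = 0 always.
#'
#' @inheritParams idsDecide
#' @param balanced as in [confusionSummary()].
#' @return A [ConfusionSummary-class].
#' @export
idsConfusion <- function(outcomes, measure = "C", balanced = FALSE) {
  confusionFromDecisions(
    idsDecide(outcomes, measure), outcomes$targetPresent,
    balanced = balanced
  )
}

#' As published: reference human/monkey/IDS performance table
#'
#' The printed comparison rows for rapid yes/no categorization: monkey
#' experiments on new and familiar images, human experiments on full and
#' parafovea-cropped images, and the Ideal Decision Stage driven by the
#' best saliency algorithm's measure-C hit rate (0.70). Reproduced verbatim
#' as published data, including the familiar-images row whose printed TN
#' (0.83) and FP (0.31) do not sum to 1 — kept as data, not corrected.
#'
#' @return data.frame with columns \code{group}, \code{condition},
#'   \code{accuracy}, \code{tp}, \code{fn}, \code{tn}, \code{fp}.
#' @export
referencePerformance <- function() {
  data.frame(
    group = c("monkey", "monkey", "human", "human", "ids"),
    condition = c(
      "new images", "familiar images",
      "full images", "cropped images", "full images"
    ),
    accuracy = c(0.84, 0.89, 0.93, 0.85, 0.85),
    tp = c(0.99, 0.96, 0.94, 0.88, 0.70),
    fn = c(0.01, 0.04, 0.06, 0.12, 0.30),
    tn = c(0.69, 0.83, 0.93, 0.85, 1.00),
    fp = c(0.31, 0.31, 0.07, 0.15, 0.00),
    stringsAsFactors = FALSE
  )
}

#' Processing-depth metadata for published saliency algorithms
#'
#' Static annotation table: approximate neural-equivalent processing depth
#' of the eight published saliency algorithms whose maps this package can
#' evaluate (their maps are consumed as input files; none is reimplemented
#' here). Used only to annotate reports against the roughly-15-layer
#' feedforward plausibility bound.
#'
#' @return data.frame with columns \code{algorithm} and \code{depth}.
#' @export
saliencyAlgorithmDepths <- function() {
  data.frame(
    algorithm = c(
      "AIM", "BMS", "ITTI", "eDN", "OBJ", "RARE2012",
      "oSALICON", "DeepGazeII"
    ),
    depth = c(3L, 4L, 3L, 4L, 6L, 7L, 16L, 19L),
    stringsAsFactors = FALSE
  )
}
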