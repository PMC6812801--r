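#' Configure the synthetic stimulus generator
#'
#' Builds a [SynthConfig-class], optionally starting from a preset that
#' emulates the structure of the two classic rapid-categorization stimulus
#' collections (which are privately held and not redistributable):
#' \describe{
#'   \item{\code{"thorpe-like"}}{2000 images of 256 x 384, 996 target-present,
#'     strong centre bias (centroid spread 1.35 degrees, chosen so ~94
#'     percent of targets have at least 27 percent of their area inside the
#'     2.5-degree parafovea).}
#'   \item{\code{"potter-like"}}{1711 images of 200 x 300, 366 target-present,
#'     substantial but weaker centre bias (spread 4 degrees; in-frame
#'     truncation caps how diffuse the centroids can be, giving ~75-78
#'     percent of targets at least 41 percent inside the parafovea, close
#'     to the 73 percent the emulated dataset exhibits).}
#' }
#' Target areas are uniform on roughly 1-10 percent of the image area; the
#' emulated datasets report no target-size distribution, so this is a free,
#' documented choice.
#'
#' @param preset \code{"custom"}, \code{"thorpe-like"} or
#'   \code{"potter-like"}.
#' @param nImages,nTargetPresent,imageShape,centroidSpreadDeg,targetAreaPxRange,predictorAccuracy,psychMidpoint,psychSlope,seed,datasetId,geometry
#'   override any preset/default field; see [SynthConfig-class].
#' @return A validated [SynthConfig-class].
#' @examples
#' synthConfig("thorpe-like", seed = 7)
#' @export
synthConfig <- function(preset = c("custom", "thorpe-like", "potter-like"),
                        nImages = NULL, nTargetPresent = NULL,
                        imageShape = NULL, centroidSpreadDeg = NULL,
                        targetAreaPxRange = NULL, predictorAccuracy = NULL,
                        psychMidpoint = NULL, psychSlope = NULL,
                        seed = NULL, datasetId = NULL, geometry = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "thorpe-like" = list(
      nImages = 2000L, nTargetPresent = 996L, imageShape = c(256L, 384L),
      centroidSpreadDeg = 1.35, targetAreaPxRange = c(1000, 9800),
      datasetId = "thorpe-like"
    ),
    "potter-like" = list(
      nImages = 1711L, nTargetPresent = 366L, imageShape = c(200L, 300L),
      centroidSpreadDeg = 4.0, targetAreaPxRange = c(600, 6000),
      datasetId = "potter-like"
    ),
    "custom" = list(
      nImages = 100L, nTargetPresent = 50L, imageShape = c(128L, 192L),
      centroidSpreadDeg = 1.35, targetAreaPxRange = c(500, 3000),
      datasetId = "custom"
    )
  )
  pick <- function(override, default) if (is.null(override)) default else override
  new("SynthConfig",
    nImages = as.integer(pick(nImages, base$nImages)),
    nTargetPresent = as.integer(pick(nTargetPresent, base$nTargetPresent)),
    imageShape = as.integer(pick(imageShape, base$imageShape)),
    centroidSpreadDeg = as.numeric(pick(centroidSpreadDeg, base$centroidSpreadDeg)),
    targetAreaPxRange = as.numeric(pick(targetAreaPxRange, base$targetAreaPxRange)),
    predictorAccuracy = as.numeric(pick(predictorAccuracy, 0.6)),
    psychMidpoint = as.numeric(pick(psychMidpoint, 0.3)),
    psychSlope = as.numeric(pick(psychSlope, 10)),
    seed = as.integer(pick(seed, 1L)),
    datasetId = as.character(pick(datasetId, base$datasetId)),
    geometry = pick(geometry, ViewingGeometry())
  )
}

# rasterize an axis-aligned ellipse (semi-axes a rows, b cols) on pixel centres
ellipseMask <- function(shape, center, a, b) {
  rows <- seq_len(shape[1]) - 1
  cols <- seq_len(shape[2]) - 1
  outer(((rows - center[1]) / a)^2, ((cols - center[2]) / b)^2, "+") <= 1
}

#' Generate a synthetic stimulus set
#'
#' Target-present images contain one axis-aligned elliptical blob target on
#' a low-amplitude textured background; the ground-truth mask is the exact
#' blob support. Target centroids follow an isotropic Gaussian (in degrees
#' of visual angle) about the image centre, truncated by rejection so the
#' whole target fits in-frame; a spread of zero puts every centroid exactly
#' at the centre. Target-absent images are background only. With a fixed
#' config the output is bit-identical across calls; pixel data is generated
#' only on request since only image-based predictors need it.
#'
#' @param config a [SynthConfig-class].
#' @param images generate pixel data (background + blob) as well as masks.
#' @param dir optional directory: write PNGs and a manifest CSV readable by
#'   [loadManifest()].
#' @return A [StimulusSet-class]. The manifest gains generator ground-truth
#'   columns \code{centroidRow}, \code{centroidCol}, \code{areaPx}
#'   (\code{NA} for target-absent rows).
#' @export
generateDataset <- function(config, images = FALSE, dir = NULL) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  shape <- config@imageShape
  n <- config@nImages
  nPos <- config@nTargetPresent
  sigmaPx <- config@centroidSpreadDeg * pxPerDegree(config@geometry)
  ctr <- imageCenter(shape)
  makeImages <- images || !is.null(dir)
  ids <- sprintf("img%05d", seq_len(n))
  present <- c(rep(TRUE, nPos), rep(FALSE, n - nPos))

  masksList <- list()
  imagesList <- list()
  centroidRow <- rep(NA_real_, n)
  centroidCol <- rep(NA_real_, n)
  areaPx <- rep(NA_integer_, n)

  # target geometry (stream "dataset") is drawn independently of pixel
  # synthesis (stream "images"), so masks are bit-identical whether or not
  # pixel data is requested
  geoms <- withSeed(deriveSeed(config@seed, "dataset"), {
    lapply(seq_len(n), function(i) {
      if (!present[i]) {
        return(NULL)
      }
      area <- stats::runif(
        1, config@targetAreaPxRange[1],
        config@targetAreaPxRange[2]
      )
      asp <- exp(stats::runif(1, -0.5, 0.5))
      a <- sqrt(area * asp / pi)
      b <- sqrt(area / (asp * pi))
      cen <- NULL
      for (try in seq_len(1000L)) {
        cand <- ctr + stats::rnorm(2, 0, sigmaPx)
        if (cand[1] - a >= 0 && cand[1] + a <= shape[1] - 1 &&
          cand[2] - b >= 0 && cand[2] + b <= shape[2] - 1) {
          cen <- cand
          break
        }
      }
      if (is.null(cen)) { # extreme spread: clamp into the feasible box
        cand <- ctr + stats::rnorm(2, 0, sigmaPx)
        cen <- pmin(pmax(cand, c(a, b)), c(shape[1] - 1 - a, shape[2] - 1 - b))
      }
      list(a = a, b = b, cen = cen)
    })
  })

  for (i in seq_len(n)) {
    if (!present[i]) next
    g <- geoms[[i]]
    mk <- ellipseMask(shape, g$cen, g$a, g$b)
    if (!any(mk)) { # sub-pixel target: force the centroid pixel
      mk[round(g$cen[1]) + 1L, round(g$cen[2]) + 1L] <- TRUE
    }
    masksList[[ids[i]]] <- mk
    st <- maskStats(mk)
    centroidRow[i] <- st$centroid[1]
    centroidCol[i] <- st$centroid[2]
    areaPx[i] <- st$area
  }

  if (makeImages) {
    rows <- seq_len(shape[1]) - 1
    cols <- seq_len(shape[2]) - 1
    imagesList <- withSeed(deriveSeed(config@seed, "images"), {
      out <- vector("list", n)
      names(out) <- ids
      for (i in seq_len(n)) {
        noise <- matrix(stats::runif(prod(shape)), shape[1], shape[2])
        smooth <- EBImage::gblur(noise, sigma = 3)
        smooth <- (smooth - mean(smooth)) / max(stats::sd(smooth), 1e-12)
        bg <- 0.45 + 0.06 * smooth
        if (present[i]) {
          g <- geoms[[i]]
          bump <- exp(-2 * outer(
            ((rows - g$cen[1]) / g$a)^2,
            ((cols - g$cen[2]) / g$b)^2, "+"
          ))
          bg <- bg + 0.5 * bump * masksList[[ids[i]]]
        }
        out[[i]] <- pmin(pmax(bg, 0), 1)
      }
      out
    })
  }

  man <- data.frame(
    id = ids, image = NA_character_, mask = NA_character_,
    targetPresent = present, dataset = config@datasetId,
    centroidRow = centroidRow, centroidCol = centroidCol, areaPx = areaPx,
    stringsAsFactors = FALSE
  )
  set <- new("StimulusSet",
    manifest = man, masks = masksList, images = imagesList,
    imageShape = shape
  )
  if (!is.null(dir)) {
    manifestPath <- writeStimulusSet(set, dir)
    message("wrote ", n, " stimuli to ", dirname(manifestPath))
  }
  set
}

#' Synthetic point predictor of controllable accuracy
#'
#' A stand-in for a saliency algorithm's predicted point: on a
#' target-present image the point falls uniformly inside the target mask
#' with probability q and uniformly over the whole image otherwise; on a
#' target-absent image it always falls uniformly over the image. Its
#' expected measure-A hit rate is therefore
#' q + (1 - q) * E[target area / image area].
#'
#' @param set a [StimulusSet-class].
#' @param q probability of an informed (in-target) draw.
#' @param seed integer seed (private stream; caller RNG untouched).
#' @return data.frame with columns \code{id}, \code{pRow}, \code{pCol}.
#' @export
syntheticPredictor <- function(set, q, seed) {
  stopifnot(is(set, "StimulusSet"), q >= 0, q <= 1)
  man <- set@manifest
  shape <- set@imageShape
  withSeed(seed, {
    pRow <- integer(nrow(man))
    pCol <- integer(nrow(man))
    for (i in seq_len(nrow(man))) {
      informed <- man$targetPresent[i] && stats::runif(1) < q
      if (informed) {
        idx <- which(set@masks[[man$id[i]]], arr.ind = TRUE)
        k <- sample.int(nrow(idx), 1L)
        pRow[i] <- idx[k, 1] - 1L
        pCol[i] <- idx[k, 2] - 1L
      } else {
        pRow[i] <- sample.int(shape[1], 1L) - 1L
        pCol[i] <- sample.int(shape[2], 1L) - 1L
      }
    }
    data.frame(
      id = man$id, pRow = pRow, pCol = pCol,
      stringsAsFactors = FALSE
    )
  })
}

#' Synthetic psychometric responses
#'
#' Correctness is Bernoulli with success probability
#' \code{plogis((overlap - midpoint) * slope)}: a logistic link between the
#' fraction of the target inside the parafovea and the probability of a
#' correct categorization. An infinite slope gives a step function at the
#' midpoint; slope zero gives chance (0.5) everywhere.
#'
#' @param overlaps vector of overlap fractions in [0, 1].
#' @param midpoint overlap at which accuracy crosses 0.5.
#' @param slope steepness of the logistic link.
#' @param seed integer seed.
#' @return Logical vector of simulated correctness.
#' @export
syntheticResponses <- function(overlaps, midpoint = 0.3, slope = 10, seed) {
  stopifnot(all(overlaps >= 0), all(overlaps <= 1), slope >= 0)
  p <- stats::plogis((overlaps - midpoint) * slope)
  withSeed(seed, stats::runif(length(overlaps)) < p)
}

#' Simulate a multi-subject trial table
#'
#' One simulated response per subject per stimulus, suitable for
#' [binAccuracyByOverlap()]. Each subject gets an independent response
#' stream derived from the seed.
#'
#' @param overlaps per-stimulus overlap fractions.
#' @param ids per-stimulus ids (recycled names if missing).
#' @param nSubjects number of simulated subjects.
#' @param midpoint,slope psychometric parameters, as in
#'   [syntheticResponses()].
#' @param condition condition label stored on every trial.
#' @param seed integer seed.
#' @return data.frame with columns \code{subject}, \code{id},
#'   \code{condition}, \code{overlap}, \code{correct}.
#' @export
syntheticTrials <- function(overlaps, ids = NULL, nSubjects = 17L,
                            midpoint = 0.3, slope = 10,
                            condition = "full", seed) {
  if (is.null(ids)) {
    ids <- sprintf("img%05d", seq_along(overlaps))
  }
  stopifnot(length(ids) == length(overlaps), nSubjects >= 1L)
  do.call(rbind, lapply(seq_len(nSubjects), function(s) {
    data.frame(
      subject = sprintf("s%02d", s),
      id = ids,
      condition = condition,
      overlap = overlaps,
      correct = syntheticResponses(overlaps, midpoint, slope,
        seed = (deriveSeed(seed, "responses") + s) %% (2^31 - 1)
      ),
      stringsAsFactors = FALSE
    )
  }))
}

#' Recover psychometric parameters from binned accuracies
#'
#' Aggregates trials into equal-width overlap bins and fits a binomial GLM
#' with logit link of per-bin correct counts on bin midpoints. The
#' recovered midpoint is -intercept / slope.
#'
#' @param trials trial data.frame as produced by [syntheticTrials()] (or
#'   any with \code{overlap} and \code{correct}).
#' @param nBins number of bins on (0, 1].
#' @return List with \code{midpoint}, \code{slope} and the per-bin counts
#'   used for the fit.
#' @export
fitPsychometric <- function(trials, nBins = 10L) {
  stopifnot(all(c("overlap", "correct") %in% names(trials)))
  bin <- overlapBin(trials$overlap, as.integer(nBins))
  keep <- !is.na(bin)
  k <- tapply(trials$correct[keep], bin[keep], sum)
  n <- tapply(rep(1L, sum(keep)), bin[keep], sum)
  mids <- (as.integer(names(k)) - 0.5) / nBins
  if (length(k) < 2L) {
    stop("need trials in at least two bins to fit a psychometric function")
  }
  fit <- stats::glm(
    cbind(k, n - k) ~ mids,
    family = stats::binomial()
  )
  b <- stats::coef(fit)
  list(
    midpoint = unname(-b[1] / b[2]),
    slope = unname(b[2]),
    bins = data.frame(mid = mids, k = as.integer(k), n = as.integer(n))
  )
}
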