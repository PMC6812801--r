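#' Run the full evaluation pipeline
#'
#' Orchestrates generate (or load) -> predict -> evaluate -> analyze into a
#' reproducible run directory of CSV tables. Stages: stimulus set (a
#' synthetic preset or a manifest on disk), one predicted point per image
#' per predictor, the four hit measures and overlap fractions, per-measure
#' summary rates, threshold-sensitivity curves, centre-bias summaries of
#' targets and predictions, an Ideal Decision Stage confusion table, the
#' algorithmic accuracy-by-overlap binning, and a simulated multi-subject
#' binned accuracy table. Reruns with the same configuration produce
#' byte-identical outputs.
#'
#' @param config a named list, or the path of a YAML/JSON file holding one.
#'   Recognized keys (all optional): \code{dataset} (a [synthConfig()]
#'   preset name, default \code{"custom"}, or a manifest CSV path),
#'   \code{geometry} (list with \code{distance_cm}, \code{diagonal_inch},
#'   \code{resolution} = c(width, height)), \code{radius_deg} (default
#'   2.5), \code{predictors} (subset of \code{"center"}, \code{"random"},
#'   \code{"contrast"}), \code{thresholds} (named fractions, default
#'   C = 0.27, D = 0.41), \code{sensitivity_grid}, \code{n_subjects},
#'   \code{psych_midpoint}, \code{psych_slope}, \code{predictor_q},
#'   \code{seed}, and generator overrides \code{n_images},
#'   \code{n_target_present}. Unknown keys are an error.
#' @param outDir run directory to create (default: a fresh directory under
#'   \code{tempdir()}).
#' @return Invisibly, a list with the run directory path, the evaluated
#'   outcome tables per predictor, and the summary data.frame.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c(
    "dataset", "geometry", "radius_deg", "predictors", "thresholds",
    "sensitivity_grid", "n_subjects", "psych_midpoint", "psych_slope",
    "predictor_q", "seed", "n_images", "n_target_present"
  )
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("invalid config keys: ", paste(bad, collapse = ", "))
  }
  pick <- function(key, default) {
    if (is.null(config[[key]])) default else config[[key]]
  }
  seed <- as.integer(pick("seed", 1L))
  geometry <- if (is.null(config$geometry)) {
    ViewingGeometry()
  } else {
    g <- config$geometry
    ViewingGeometry(
      distanceCm = g$distance_cm %||% 57,
      diagonalInch = g$diagonal_inch %||% 23,
      resWidthPx = (g$resolution %||% c(1920, 1080))[1],
      resHeightPx = (g$resolution %||% c(1920, 1080))[2]
    )
  }
  predictors <- match.arg(
    pick("predictors", c("center", "random")),
    c("center", "random", "contrast"),
    several.ok = TRUE
  )
  thresholds <- unlist(pick("thresholds", c(C = 0.27, D = 0.41)))
  grid <- pick("sensitivity_grid", seq(0, 1, by = 0.05))
  nSubjects <- as.integer(pick("n_subjects", 17L))
  needImages <- "contrast" %in% predictors

  if (is.null(outDir)) {
    outDir <- tempfile("parafovea-run-")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  datasetKey <- pick("dataset", "custom")
  if (datasetKey %in% c("custom", "thorpe-like", "potter-like")) {
    synth <- synthConfig(datasetKey,
      seed = seed,
      nImages = config$n_images, nTargetPresent = config$n_target_present,
      predictorAccuracy = config$predictor_q,
      psychMidpoint = config$psych_midpoint,
      psychSlope = config$psych_slope,
      geometry = geometry
    )
    message("generating '", datasetKey, "' stimulus set (seed ", seed, ")")
    set <- generateDataset(synth, images = needImages)
    psychMidpoint <- synth@psychMidpoint
    psychSlope <- synth@psychSlope
    predictorQ <- synth@predictorAccuracy
  } else {
    message("loading manifest ", datasetKey)
    set <- loadManifest(datasetKey, loadImages = needImages)
    psychMidpoint <- as.numeric(pick("psych_midpoint", 0.3))
    psychSlope <- as.numeric(pick("psych_slope", 10))
    predictorQ <- as.numeric(pick("predictor_q", 0.6))
  }
  man <- manifest(set)
  shape <- imageShape(set)
  spec <- ParafoveaSpec(
    center = imageCenter(shape),
    radiusDeg = as.numeric(pick("radius_deg", 2.5)),
    geometry = geometry
  )
  message(sprintf(
    "%d images (%d target-present), parafovea %.2f px",
    nrow(man), sum(man$targetPresent), radiusPx(spec)
  ))

  predict1 <- function(name) {
    switch(name,
      center = {
        p <- unname(centerPredictor(shape))
        data.frame(id = man$id, pRow = p[1], pCol = p[2])
      },
      random = {
        pts <- uniformRandomPredictor(shape,
          n = nrow(man),
          seed = deriveSeed(seed, "predictor")
        )
        data.frame(id = man$id, pRow = pts[, 1], pCol = pts[, 2])
      },
      contrast = {
        pts <- t(vapply(
          man$id,
          function(id) peakLocation(contrastBaseline(images(set)[[id]])),
          numeric(2)
        ))
        data.frame(id = man$id, pRow = pts[, 1], pCol = pts[, 2])
      }
    )
  }

  outcomesList <- list()
  summaryRows <- list()
  for (pr in predictors) {
    message("predictor '", pr, "'")
    preds <- predict1(pr)
    utils::write.csv(preds, file.path(outDir, paste0("predictions_", pr, ".csv")),
      row.names = FALSE
    )
    oc <- evaluateDataset(set, preds, spec, thresholds)
    outcomesList[[pr]] <- oc
    utils::write.csv(oc, file.path(outDir, paste0("outcomes_", pr, ".csv")),
      row.names = FALSE
    )
    rates <- datasetHitRates(oc)
    summaryRows[[pr]] <- data.frame(
      dataset = man$dataset[1], predictor = pr,
      measure = sub("^hit", "", names(rates)), hitRatePct = unname(rates)
    )
    utils::write.csv(sensitivityCurve(oc, grid),
      file.path(outDir, paste0("sensitivity_", pr, ".csv")),
      row.names = FALSE
    )
    ids <- idsConfusion(oc, measure = if ("C" %in% names(thresholds)) "C" else "B")
    utils::write.csv(
      data.frame(
        predictor = pr, accuracy = accuracy(ids), t(rates(ids)),
        nPos = ids@nPos, nNeg = ids@nNeg
      ),
      file.path(outDir, paste0("ids_", pr, ".csv")),
      row.names = FALSE
    )
    utils::write.csv(algorithmAccuracyByOverlap(oc),
      file.path(outDir, paste0("bins_", pr, ".csv")),
      row.names = FALSE
    )
    ps <- predictionScatter(
      as.matrix(oc[, c("pRow", "pCol")]), shape, spec,
      geometry,
      targetPresent = oc$targetPresent
    )
    utils::write.csv(
      do.call(rbind, lapply(names(ps), function(grp) {
        s <- ps[[grp]]
        data.frame(
          predictor = pr, group = grp, n = s$n,
          meanRow = s$meanCentroid[1], meanCol = s$meanCentroid[2],
          fractionInParafovea = s$fractionInParafovea,
          centerOffsetPx = s$centerOffsetPx,
          centerOffsetDeg = s$centerOffsetDeg
        )
      })),
      file.path(outDir, paste0("bias_predictions_", pr, ".csv")),
      row.names = FALSE
    )
  }

  # target centre-bias summary
  if (length(masks(set))) {
    cs <- centroidScatter(masks(set), spec, geometry)
    utils::write.csv(
      data.frame(
        dataset = man$dataset[1], n = cs$n,
        meanRow = cs$meanCentroid[1], meanCol = cs$meanCentroid[2],
        fractionInParafovea = cs$fractionInParafovea,
        centerOffsetPx = cs$centerOffsetPx,
        centerOffsetDeg = cs$centerOffsetDeg
      ),
      file.path(outDir, "bias_targets.csv"),
      row.names = FALSE
    )
  }

  # simulated human accuracy-by-overlap analysis
  presentMan <- man[man$targetPresent, , drop = FALSE]
  if (nrow(presentMan)) {
    disc <- parafoveaMask(shape, spec)
    overlaps <- vapply(
      presentMan$id,
      function(id) overlapFraction(masks(set)[[id]], disc), numeric(1)
    )
    trials <- syntheticTrials(overlaps, presentMan$id,
      nSubjects = nSubjects,
      midpoint = psychMidpoint, slope = psychSlope, seed = seed
    )
    ba <- binAccuracyByOverlap(trials)
    utils::write.csv(ba$stats, file.path(outDir, "human_bins.csv"),
      row.names = FALSE
    )
  }

  summary <- do.call(rbind, summaryRows)
  rownames(summary) <- NULL
  utils::write.csv(summary, file.path(outDir, "summary.csv"),
    row.names = FALSE
  )
  runInfo <- list(
    seed = seed, dataset = datasetKey,
    predictors = predictors, predictor_q = predictorQ,
    radius_deg = radiusDeg(spec), radius_px = radiusPx(spec),
    thresholds = as.list(thresholds),
    n_images = nrow(man), n_target_present = sum(man$targetPresent),
    n_subjects = nSubjects,
    psych_midpoint = psychMidpoint, psych_slope = psychSlope,
    geometry = list(
      distance_cm = geometry@distanceCm,
      diagonal_inch = geometry@diagonalInch,
      resolution = c(geometry@resWidthPx, geometry@resHeightPx)
    )
  )
  yaml::write_yaml(runInfo, file.path(outDir, "run_info.yaml"))
  message("run written to ", outDir)
  invisible(list(dir = outDir, outcomes = outcomesList, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
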