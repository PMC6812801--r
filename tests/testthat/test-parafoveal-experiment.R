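test_that("parafoveal cropping keeps the disc and fills the surround", {
  set.seed(2)
  img <- matrix(runif(50 * 60), 50, 60)
  discAll <- matrix(TRUE, 50, 60)
  expect_identical(cropToParafovea(img, discAll), img)
  disc <- parafoveaMask(c(50, 60), c(24.5, 29.5), 12)
  out <- cropToParafovea(img, disc, fill = 0.8)
  expect_true(all(out[!disc] == 0.8))
  expect_identical(out[disc], img[disc]) # in-disc checksum unchanged
  expect_equal(sum(out[disc]), sum(img[disc]))
  # channelwise on an RGB array
  rgb <- array(runif(50 * 60 * 3), c(50, 60, 3))
  outRgb <- cropToParafovea(rgb, disc, fill = c(0.7, 0.8, 0.9))
  expect_true(all(outRgb[, , 2][!disc] == 0.8))
  expect_identical(outRgb[, , 1][disc], rgb[, , 1][disc])
  expect_error(cropToParafovea(img, disc[1:10, ]), "shape")
})

test_that("binned accuracy reproduces closed-form box statistics", {
  # per-subject accuracies {0.8, 1.0, 0.9} in the top overlap bin
  trials <- data.frame(
    subject = c(rep("s1", 5), rep("s2", 4), rep("s3", 10)),
    overlap = 0.95,
    correct = c(
      rep(TRUE, 4), FALSE, # 0.8
      rep(TRUE, 4), # 1.0
      rep(TRUE, 9), FALSE # 0.9
    )
  )
  ba <- binAccuracyByOverlap(trials)
  st <- ba$stats[10, ]
  expect_equal(st$n, 3L)
  expect_equal(st$median, 0.9)
  # quantile-oracle equivalence for the quartiles
  expect_equal(st$q1, unname(quantile(c(0.8, 1, 0.9), 0.25)))
  expect_equal(st$q3, unname(quantile(c(0.8, 1, 0.9), 0.75)))
  # all other bins empty and flagged
  expect_true(all(ba$stats$n[1:9] == 0L))
  expect_true(all(is.na(ba$stats$median[1:9])))
  expect_error(binAccuracyByOverlap(trials, nBins = 0), "positive")
})

test_that("binning conserves trials and matches brute-force quantiles", {
  set.seed(6)
  n <- 400
  trials <- data.frame(
    subject = sample(sprintf("s%02d", 1:10), n, TRUE),
    overlap = runif(n),
    correct = runif(n) > 0.3
  )
  ba <- binAccuracyByOverlap(trials)
  expect_equal(sum(ba$stats$nTrials), sum(trials$overlap > 0))
  # brute-force per-bin recount
  for (b in 1:10) {
    sel <- trials$overlap > (b - 1) / 10 & trials$overlap <= b / 10
    expect_equal(ba$stats$nTrials[b], sum(sel))
    if (any(sel)) {
      acc <- tapply(trials$correct[sel], trials$subject[sel], mean)
      acc <- as.numeric(acc[!is.na(acc)])
      expect_equal(ba$stats$median[b], unname(quantile(acc, 0.5)))
      q <- quantile(acc, c(0.25, 0.75), names = FALSE)
      iqr <- diff(q)
      inside <- acc[acc >= q[1] - 1.5 * iqr & acc <= q[2] + 1.5 * iqr]
      expect_equal(ba$stats$whiskerLow[b], min(inside))
      expect_equal(ba$stats$whiskerHigh[b], max(inside))
    }
  }
})

test_that("a logistic psychometric link gives rising bin medians", {
  set.seed(10)
  overlaps <- runif(600)
  trials <- syntheticTrials(overlaps,
    nSubjects = 12, midpoint = 0.4,
    slope = 8, seed = 44
  )
  ba <- binAccuracyByOverlap(trials)
  med <- ba$stats$median
  expect_true(all(!is.na(med)))
  # monotone trend up to sampling noise: strong rank correlation
  expect_gt(cor(seq_along(med), med, method = "spearman"), 0.8)
})

test_that("algorithmic accuracy-by-overlap matches its analytic expectations", {
  set <- tinySet(nImages = 80, nPresent = 60, seed = 19, shape = c(100L, 150L))
  man <- manifest(set)
  # a predictor always inside the target: 100% in every nonempty bin
  inPts <- t(vapply(man$id, function(id) {
    if (is.na(man$areaPx[match(id, man$id)])) {
      return(c(0, 0))
    }
    idx <- which(masks(set)[[id]], arr.ind = TRUE)[1, ]
    c(idx[1] - 1, idx[2] - 1)
  }, numeric(2)))
  predsIn <- data.frame(id = man$id, pRow = inPts[, 1], pCol = inPts[, 2])
  ocIn <- evaluateDataset(set, predsIn, discSpec(imageCenter(c(100, 150)), 40))
  binsIn <- algorithmAccuracyByOverlap(ocIn)
  expect_true(all(binsIn$hitRate[binsIn$n > 0] == 100))
  expect_equal(sum(binsIn$n), sum(ocIn$targetPresent & ocIn$overlapFraction > 0))
  # a uniform random predictor: overall rate near the mean mask area share
  pts <- uniformRandomPredictor(imageShape(set), n = nrow(man), seed = 55)
  predsU <- data.frame(id = man$id, pRow = pts[, 1], pCol = pts[, 2])
  ocU <- evaluateDataset(set, predsU)
  expected <- mean(man$areaPx[man$targetPresent]) / prod(imageShape(set))
  rate <- unname(datasetHitRates(ocU)["hitA"]) / 100
  se <- sqrt(expected * (1 - expected) / 60)
  expect_lt(abs(rate - expected), 4 * se + 0.02)
  expect_error(algorithmAccuracyByOverlap(ocU[!ocU$targetPresent, ]), "target-present")
})
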