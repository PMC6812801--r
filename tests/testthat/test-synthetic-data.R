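test_that("presets reproduce the emulated dataset structure", {
  thorpe <- synthConfig("thorpe-like")
  expect_equal(thorpe@nImages, 2000L)
  expect_equal(thorpe@nTargetPresent, 996L)
  expect_equal(thorpe@imageShape, c(256L, 384L))
  potter <- synthConfig("potter-like")
  expect_equal(potter@nImages, 1711L)
  expect_equal(potter@nTargetPresent, 366L)
  expect_equal(potter@imageShape, c(200L, 300L))
  expect_error(synthConfig("custom", nTargetPresent = 101L), "nImages")
  expect_error(
    synthConfig("custom", targetAreaPxRange = c(1e5, 1e6)),
    "larger than the image"
  )
})

test_that("a generated set is internally consistent", {
  set <- tinySet(nImages = 25, nPresent = 10, seed = 2)
  man <- manifest(set)
  expect_equal(nrow(man), 25L)
  expect_equal(sum(man$targetPresent), 10L)
  expect_length(masks(set), 10L)
  for (id in names(masks(set))) {
    st <- maskStats(masks(set)[[id]])
    i <- match(id, man$id)
    expect_equal(st$area, man$areaPx[i])
    expect_equal(unname(st$centroid), c(man$centroidRow[i], man$centroidCol[i]))
  }
})

test_that("zero centroid spread pins every target to the image centre", {
  set <- generateDataset(synthConfig("custom",
    nImages = 6, nTargetPresent = 6, imageShape = c(64L, 64L),
    centroidSpreadDeg = 0, targetAreaPxRange = c(100, 101), seed = 4
  ))
  ctr <- imageCenter(c(64, 64))
  man <- manifest(set)
  expect_true(all(abs(man$centroidRow - ctr[1]) < 1))
  expect_true(all(abs(man$centroidCol - ctr[2]) < 1))
})

test_that("the generator is bit-identical under a fixed seed", {
  a <- tinySet(seed = 12)
  b <- tinySet(seed = 12)
  expect_identical(manifest(a), manifest(b))
  expect_identical(masks(a), masks(b))
  c <- tinySet(seed = 13)
  expect_false(identical(masks(a), masks(c)))
  # masks do not depend on whether pixel data is generated
  d <- tinySet(seed = 12, images = TRUE)
  expect_identical(masks(a), masks(d))
  # and the image stream itself is reproducible
  e <- tinySet(seed = 12, images = TRUE)
  expect_identical(images(d), images(e))
})

test_that("predictor accuracy q maps onto the measure-A hit rate", {
  set <- tinySet(nImages = 120, nPresent = 100, seed = 7, shape = c(100L, 150L))
  man <- manifest(set)
  # q = 1: always inside the target
  oc1 <- evaluateDataset(set, syntheticPredictor(set, q = 1, seed = 1))
  expect_equal(unname(datasetHitRates(oc1)["hitA"]), 100)
  # q = 0: the rate approaches the mean target area share
  oc0 <- evaluateDataset(set, syntheticPredictor(set, q = 0, seed = 2))
  expected0 <- mean(man$areaPx[man$targetPresent]) / prod(imageShape(set))
  se0 <- sqrt(expected0 * (1 - expected0) / 100)
  expect_lt(abs(datasetHitRates(oc0)["hitA"] / 100 - expected0), 4 * se0 + 0.01)
  # determinism and independence of streams
  p1 <- syntheticPredictor(set, q = 0.5, seed = 99)
  p2 <- syntheticPredictor(set, q = 0.5, seed = 99)
  expect_identical(p1, p2)
})

test_that("synthetic responses follow the logistic link in its limits", {
  ov <- seq(0, 1, by = 0.01)
  # near-infinite slope: step at the midpoint
  step <- syntheticResponses(ov, midpoint = 0.3, slope = 1e6, seed = 1)
  expect_true(all(step[ov > 0.31]))
  expect_true(all(!step[ov < 0.29]))
  # slope zero: chance performance
  flat <- syntheticResponses(rep(0.9, 4000), midpoint = 0.3, slope = 0, seed = 2)
  expect_lt(abs(mean(flat) - 0.5), 0.03)
  expect_identical(
    syntheticResponses(ov, seed = 5),
    syntheticResponses(ov, seed = 5)
  )
})

test_that("psychometric parameters are recoverable from binned accuracies", {
  set.seed(30)
  overlaps <- runif(800)
  trials <- syntheticTrials(overlaps,
    nSubjects = 10, midpoint = 0.35,
    slope = 9, seed = 66
  )
  fit <- fitPsychometric(trials)
  expect_lt(abs(fit$midpoint - 0.35), 0.05)
  expect_gt(fit$slope, 0)
  expect_equal(sum(fit$bins$n), sum(trials$overlap > 0))
})
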