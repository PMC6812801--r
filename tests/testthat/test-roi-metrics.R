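test_that("overlap fraction counts pixels exactly", {
  disc <- parafoveaMask(c(60, 60), c(30, 30), 20)
  inside <- maskFromPoints(c(60, 60), cbind(c(30, 31), c(30, 31)))
  expect_equal(overlapFraction(inside, disc), 1)
  outside <- maskFromPoints(c(60, 60), cbind(c(0, 1), c(0, 1)))
  expect_equal(overlapFraction(outside, disc), 0)
  expect_error(overlapFraction(matrix(FALSE, 60, 60), disc), "empty")
})

test_that("a square mask centred on the disc boundary is about half inside", {
  # large disc so its boundary is locally straight across the square
  disc <- parafoveaMask(c(400, 400), c(199.5, 10), 150)
  sq <- matrix(FALSE, 400, 400)
  sq[181:220, 141:180] <- TRUE # 40x40 centred at (200, 160) = boundary
  expect_equal(overlapFraction(sq, disc), 0.5, tolerance = 0.05)
})

test_that("graded measures nest and respect the point-membership rule", {
  disc <- parafoveaMask(c(50, 50), c(24.5, 24.5), 10)
  # 4-pixel mask with exactly 1 pixel inside the disc: overlap 0.25
  mk <- maskFromPoints(c(50, 50), cbind(c(24, 24, 24, 24), c(20, 2, 3, 4)))
  expect_equal(overlapFraction(mk, disc), 0.25)
  hit <- evaluatePoint(c(24, 20), mk, disc)
  expect_true(hit$hitA)
  expect_true(hit$hitB)
  expect_false(any(hit$hitAtThreshold)) # 0.25 < 0.27 < 0.41
  # same mask, point inside the mask but outside the disc: A only
  hitOut <- evaluatePoint(c(24, 2), mk, disc)
  expect_true(hitOut$hitA)
  expect_false(hitOut$hitB)
  # point off the mask entirely: everything misses
  miss <- evaluatePoint(c(0, 0), mk, disc)
  expect_false(miss$hitA || miss$hitB || any(miss$hitAtThreshold))
  expect_error(evaluatePoint(c(60, 0), mk, disc), "outside")
})

test_that("measure nesting D => C => B => A holds on random outcomes", {
  set.seed(77)
  shape <- c(40, 60)
  disc <- parafoveaMask(shape, c(19.5, 29.5), 12)
  for (i in 1:50) {
    npx <- sample(1:80, 1)
    mk <- maskFromPoints(shape, cbind(
      sample(0:(shape[1] - 1), npx, TRUE),
      sample(0:(shape[2] - 1), npx, TRUE)
    ))
    p <- c(sample(0:(shape[1] - 1), 1), sample(0:(shape[2] - 1), 1))
    h <- evaluatePoint(p, mk, disc)
    expect_true(!h$hitAtThreshold[["D"]] || h$hitAtThreshold[["C"]])
    expect_true(!h$hitAtThreshold[["C"]] || h$hitB)
    expect_true(!h$hitB || h$hitA)
  }
})

test_that("dataset hit rates are plain percentages over target-present images", {
  oc <- data.frame(
    targetPresent = c(rep(TRUE, 10), FALSE, FALSE),
    overlapFraction = c(runif(10), NA, NA),
    hitA = c(rep(TRUE, 7), rep(FALSE, 3), NA, NA),
    hitB = c(rep(TRUE, 5), rep(FALSE, 5), NA, NA)
  )
  r <- datasetHitRates(oc)
  expect_equal(unname(r["hitA"]), 70)
  expect_equal(unname(r["hitB"]), 50)
  ocAll <- data.frame(targetPresent = TRUE, hitA = TRUE)
  expect_equal(unname(datasetHitRates(ocAll)["hitA"]), 100)
  expect_error(datasetHitRates(oc[11:12, ]), "no target-present")
})

test_that("sensitivity curve equals a brute-force recount and starts at B", {
  set <- tinySet(nImages = 40, nPresent = 30, seed = 13)
  preds <- syntheticPredictor(set, q = 0.7, seed = 5)
  oc <- evaluateDataset(set, preds)
  grid <- c(0, 0.1, 0.27, 0.41, 0.63, 1)
  sc <- sensitivityCurve(oc, grid)
  expect_equal(sc$hitRate[1], unname(datasetHitRates(oc)["hitB"]))
  expect_true(all(diff(sc$hitRate) <= 0))
  # brute-force recount at every grid point
  present <- oc[oc$targetPresent, ]
  for (i in seq_along(grid)) {
    n <- 0L
    for (j in seq_len(nrow(present))) {
      if (present$hitB[j] && present$overlapFraction[j] >= grid[i]) {
        n <- n + 1L
      }
    }
    expect_equal(sc$hitRate[i], 100 * n / nrow(present))
  }
  # rate at 1.0 counts only fully enclosed targets with B hits
  full <- present$hitB & present$overlapFraction >= 1
  expect_equal(sc$hitRate[length(grid)], 100 * mean(full))
  expect_error(sensitivityCurve(oc, c(0.1, 0.5)), "include 0")
  expect_error(sensitivityCurve(oc, c(0, 0.5, 0.3)), "increasing")
})

test_that("threshold calibration inverts the empirical survival function", {
  ov <- seq(0.1, 1, by = 0.1)
  expect_equal(calibrateThreshold(ov, 0.7), 0.4) # hand-enumerated oracle
  expect_equal(calibrateThreshold(ov, 1.0), min(ov))
  expect_equal(calibrateThreshold(ov, 0.05), max(ov))
  # the calibrated threshold achieves at least the requested coverage
  set.seed(9)
  for (i in 1:20) {
    ovs <- runif(sample(5:200, 1))
    a <- runif(1, 0.05, 1)
    t <- calibrateThreshold(ovs, a)
    expect_gte(mean(ovs >= t), a)
  }
  # non-increasing in the accuracy demand
  ovs <- runif(100)
  ts <- vapply(seq(0.1, 1, 0.1), function(a) calibrateThreshold(ovs, a), numeric(1))
  expect_true(all(diff(ts) <= 0))
  expect_error(calibrateThreshold(numeric(0), 0.5), "no overlaps")
  expect_error(calibrateThreshold(ov, 0), "humanAccuracy")
})

test_that("enlarging the parafovea never lowers B/C/D hit rates", {
  set <- tinySet(nImages = 30, nPresent = 25, seed = 23)
  preds <- syntheticPredictor(set, q = 0.8, seed = 6)
  shape <- imageShape(set)
  prev <- c(-1, -1, -1)
  for (r in c(10, 25, 45, 80)) {
    spec <- discSpec(imageCenter(shape), r)
    oc <- evaluateDataset(set, preds, spec)
    rates <- datasetHitRates(oc)[c("hitB", "hitC", "hitD")]
    expect_true(all(rates >= prev - 1e-9))
    prev <- rates
  }
})
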