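test_that("masks and images round-trip through PNG exactly", {
  d <- withr::local_tempdir()
  set.seed(1)
  mask <- matrix(runif(35 * 20) > 0.6, 35, 20)
  p <- file.path(d, "m.png")
  writeImagePNG(mask, p)
  expect_identical(readMask(p), mask)
  img <- matrix(round(runif(35 * 20) * 255) / 255, 35, 20)
  writeImagePNG(img, file.path(d, "i.png"))
  expect_equal(readImageGray(file.path(d, "i.png")), img, tolerance = 1e-9)
})

test_that("manifests load, validate and count correctly", {
  d <- withr::local_tempdir()
  mp <- writeTinyManifest(d, nImages = 3, nPresent = 2)
  suppressMessages(set <- loadManifest(mp))
  expect_s4_class(set, "StimulusSet")
  expect_equal(length(set), 3L)
  expect_equal(sum(manifest(set)$targetPresent), 2L)
  expect_length(masks(set), 2L)
  expect_length(images(set), 0L)
  suppressMessages(setImg <- loadManifest(mp, loadImages = TRUE))
  expect_length(images(setImg), 3L)
})

test_that("manifest validation rejects shape mismatches and bad rows", {
  d <- withr::local_tempdir()
  mp <- writeTinyManifest(d, nImages = 3, nPresent = 2)
  man <- read.csv(mp)
  # corrupt one mask with a wrong shape
  bad <- man$mask[man$target_present][1]
  writeImagePNG(matrix(TRUE, 5, 5), file.path(d, bad))
  expect_error(suppressMessages(loadManifest(mp)), "shape")
  # empty manifest: zero records, with a warning
  empty <- file.path(d, "empty.csv")
  write.csv(man[0, ], empty, row.names = FALSE)
  expect_warning(s0 <- loadManifest(empty), "empty")
  expect_equal(length(s0), 0L)
  # missing column
  noCol <- file.path(d, "nocol.csv")
  write.csv(man[, -2], noCol, row.names = FALSE)
  expect_error(suppressMessages(loadManifest(noCol)), "columns")
})

test_that("peak location finds the global maximum, row-major on ties", {
  m <- matrix(0, 5, 9)
  m[4, 8] <- 1
  expect_equal(unname(peakLocation(m)), c(3, 7))
  # constant map: tie broken at the origin
  expect_equal(unname(peakLocation(matrix(2, 4, 4))), c(0, 0))
  # ties: (0, 5) precedes (1, 0) in row-major order
  tie <- matrix(0, 3, 7)
  tie[1, 6] <- 3
  tie[2, 1] <- 3
  expect_equal(unname(peakLocation(tie)), c(0, 5))
  # forced hit: map equal to a mask indicator peaks inside the mask
  mask <- maskFromPoints(c(6, 6), cbind(c(2, 3), c(4, 4)))
  pk <- peakLocation(mask * 1)
  expect_true(mask[pk[1] + 1, pk[2] + 1])
  expect_error(peakLocation(matrix(NA_real_, 2, 2)), "all-NA")
  expect_error(peakLocation(numeric(0)), "matrix")
})

test_that("mask statistics give exact pixel counts and centroids", {
  allOn <- matrix(TRUE, 10, 10)
  st <- maskStats(allOn)
  expect_equal(st$area, 100L)
  expect_equal(unname(st$centroid), c(4.5, 4.5))
  one <- maskFromPoints(c(8, 8), cbind(2, 3))
  expect_equal(maskStats(one)$area, 1L)
  expect_equal(unname(maskStats(one)$centroid), c(2, 3))
  two <- maskFromPoints(c(4, 4), cbind(c(0, 0), c(0, 2)))
  expect_equal(unname(maskStats(two)$centroid), c(0, 1))
  expect_error(maskStats(matrix(FALSE, 3, 3)), "empty")
})

test_that("saliency maps load from text matrices and reject bad values", {
  d <- withr::local_tempdir()
  m <- matrix(seq(0, 1, length.out = 12), 3, 4)
  write.table(m, file.path(d, "s.txt"),
    row.names = FALSE, col.names = FALSE
  )
  expect_equal(readSaliencyMap(file.path(d, "s.txt")), m, tolerance = 1e-12)
  write.table(-m, file.path(d, "neg.txt"),
    row.names = FALSE, col.names = FALSE
  )
  expect_error(readSaliencyMap(file.path(d, "neg.txt")), "negative")
})
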