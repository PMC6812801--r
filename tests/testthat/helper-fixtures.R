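# shared fixtures: everything is generated in code, nothing is stored

figGeometry <- function() ViewingGeometry(57, 23, 1920, 1080)

# independently hand-computed trig values for the default geometry,
# frozen before the implementation was written
ORACLE_PX_PER_DEG <- 37.517247
ORACLE_R25_PX <- 93.843157

# small disc spec with an explicit pixel radius (bypasses the geometry)
discSpec <- function(center, radiusPx) {
  ParafoveaSpec(center = center, radiusDeg = 2.5, radiusPx = radiusPx)
}

# a mask from explicit 0-based (row, col) pixel coordinates
maskFromPoints <- function(shape, pts) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[pts[, 1] + 1L + pts[, 2] * shape[1]] <- TRUE
  m
}

tinySet <- function(nImages = 24, nPresent = 12, seed = 5,
                    images = FALSE, shape = c(64L, 96L)) {
  generateDataset(
    synthConfig("custom",
      nImages = nImages, nTargetPresent = nPresent,
      imageShape = shape, targetAreaPxRange = c(40, 300),
      centroidSpreadDeg = 0.4, seed = seed
    ),
    images = images
  )
}

# write a small PNG stimulus directory + manifest, return the manifest path
writeTinyManifest <- function(dir, nImages = 3, nPresent = 2, seed = 8) {
  set <- tinySet(nImages, nPresent, seed = seed, images = TRUE)
  writeStimulusSet(set, dir)
}
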