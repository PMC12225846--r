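test_that("uniform scaling behaves like iterated binary morphology", {
  # an isolated pixel is erased by one erosion
  single <- squareMask(9, 5, 5)
  expect_equal(sum(applyUniformScaling(single, 1, "erode")), 0)
  # closing a solid square recovers it
  sq <- squareMask(20, 6:15, 6:15)
  closed <- applyUniformScaling(applyUniformScaling(sq, 1, "dilate"),
                                1, "erode")
  expect_identical(closed, sq)
  # eroding a solid disk strictly shrinks it
  d <- matrix(0, 21, 21)
  for (i in 1:21) for (j in 1:21) if ((i - 11)^2 + (j - 11)^2 <= 64) d[i, j] <- 1
  er <- applyUniformScaling(d, 1, "erode")
  expect_lt(sum(er), sum(d))
  expect_true(all(er <= d))
  expect_error(applyUniformScaling(sq, 0), ">= 1")
})

test_that("border fuzz only touches the dilated Sobel edge band", {
  expect_identical(applyBorderFuzz(matrix(0, 12, 12), 0.7),
                   matrix(0, 12, 12))
  sq <- squareMask(20, 6:15, 6:15)
  band <- glottisQC:::.edgeBand(sq)
  # flip_p = 1 adds the whole band
  set.seed(1)
  expect_identical(applyBorderFuzz(sq, 1),
                   glottisQC:::.asMask(sq + band > 0))
  # flip_p = 0.5 degrades IoU but never outside the band
  set.seed(2)
  fz <- applyBorderFuzz(sq, 0.5)
  expect_lt(iou(sq, fz), 1)
  changed <- which(fz != sq)
  expect_true(all(band[changed] > 0))
})

test_that("small artifacts honour count, radius and proximity bounds", {
  m <- frameMask(fixturePairs()[[2]])
  d0 <- glottisQC:::.distToForeground(m)
  set.seed(3)
  counts <- integer(0)
  for (i in 1:100) {
    out <- applySmallArtifacts(m, maxSpheres = 5, radiusRange = c(1, 3),
                               proximity = 10)
    sph <- attr(out, "spheres")
    counts <- c(counts, length(sph))
    radii <- vapply(sph, function(s) s[["radius"]], 0)
    expect_true(all(radii %in% 1:3))
    added <- which(out > 0.5 & m < 0.5)
    if (length(added)) expect_true(all(d0[added] <= 10))
  }
  expect_true(all(counts >= 1 & counts <= 5))
  expect_gt(max(counts), 1)
  # empty mask has no proximity reference and passes through unchanged
  expect_identical(applySmallArtifacts(matrix(0, 8, 8)), matrix(0, 8, 8))
})

test_that("Perlin artifacts follow the quantile threshold exactly", {
  m <- frameMask(fixturePairs()[[3]])
  set.seed(4)
  expect_identical(applyLargeArtifacts(m, 4, 1.0), m)       # nothing added
  set.seed(4)
  expect_equal(mean(applyLargeArtifacts(m, 4, 0.0)), 1)     # flooded
  set.seed(4)
  out <- applyLargeArtifacts(matrix(0, 64, 64), 4, 0.9)
  expect_equal(mean(out), 0.1, tolerance = 0.05)
  # union mode never removes original foreground
  set.seed(5)
  expect_true(all(applyLargeArtifacts(m, 4, 0.9) >= m))
})

test_that("perlin noise is smooth, seeded, and sized correctly", {
  set.seed(9)
  f1 <- perlinNoise(64, 64, 4)
  set.seed(9)
  f2 <- perlinNoise(64, 64, 4)
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(64L, 64L))
  # neighbouring pixels are close (coherent noise, not white noise)
  expect_lt(max(abs(diff(f1))), 0.2)
  expect_error(perlinNoise(63, 64, 4), "divisible")
})

test_that("degradeMask composes steps, records them, and replays exactly", {
  fp <- fixturePairs()[[1]]
  cfg <- corruptionConfig()
  off <- corruptionConfig(pApply = c(scaling = 0, borderFuzz = 0,
                                     smallArtifacts = 0,
                                     largeArtifacts = 0))
  ds0 <- degradeMask(fp, off, seed = 5)
  expect_identical(degradedMask(ds0), frameMask(fp))
  expect_equal(trueIoU(ds0), 1)
  expect_length(appliedSteps(ds0), 0)

  ds1 <- degradeMask(fp, cfg, seed = 42)
  ds2 <- degradeMask(fp, cfg, seed = 42)
  expect_identical(degradedMask(ds1), degradedMask(ds2))
  expect_identical(appliedSteps(ds1), appliedSteps(ds2))
  # stored IoU is recomputable from the masks
  expect_equal(trueIoU(ds1), iou(originalMask(ds1), degradedMask(ds1)))
  # applied steps follow the fixed pipeline order
  order4 <- c("scaling", "borderFuzz", "smallArtifacts", "largeArtifacts")
  steps <- vapply(appliedSteps(ds1), `[[`, "", "step")
  expect_identical(steps, order4[order4 %in% steps])
})

test_that("erosion-driven IoU is non-increasing in iteration count", {
  m <- frameMask(fixturePairs()[[4]])
  ious <- vapply(1:5, function(it) {
    iou(m, applyUniformScaling(m, it, "erode"))
  }, 0)
  expect_true(all(diff(ious) <= 0))
  expect_lt(ious[2], ious[1])   # strictly shrinking while mass remains
})

test_that("default corruption draws cover at least 15 of the 20 IoU bins", {
  fp <- fixturePairs()[[5]]
  cfg <- corruptionConfig()
  ious <- vapply(1:1000, function(s) {
    trueIoU(degradeMask(fp, cfg, seed = s, ensureApplied = TRUE))
  }, 0)
  expect_gte(length(unique(binIndex(ious))), 15)
})
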