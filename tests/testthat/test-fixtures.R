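test_that("glottis phantoms are valid, varied, and seeded", {
  fp <- makeGlottisPair(seed = 3)
  expect_true(validObject(fp))
  expect_gt(sum(frameMask(fp)), 0)
  expect_true(all(frameImage(fp) >= 0 & frameImage(fp) <= 255))
  expect_identical(frameMask(makeGlottisPair(seed = 3)), frameMask(fp))
  expect_identical(frameImage(makeGlottisPair(seed = 3)), frameImage(fp))
  # closed glottis: zero width -> empty mask
  closed <- makeGlottisPair(seed = 4, widthScale = 0)
  expect_equal(sum(frameMask(closed)), 0)
  # glottis size varies across subjects
  areas <- vapply(1:30, function(s) sum(frameMask(makeGlottisPair(seed = s))), 0)
  expect_gt(max(areas) / min(areas), 2)
  # the gap is darker than its surroundings
  expect_lt(mean(frameImage(fp)[frameMask(fp) > 0]),
            mean(frameImage(fp)[frameMask(fp) == 0]))
})

test_that("oscillating videos sweep area through closure with given cycles", {
  vid <- makeGlottisVideo(nFrames = 40, cycles = 2, seed = 4)
  expect_length(vid, 40)
  areas <- vapply(vid, function(f) sum(frameMask(f)), 0)
  expect_equal(min(areas), 0)                      # full closure occurs
  # count openings: maximal contiguous stretches above half the peak
  above <- areas > max(areas) / 2
  openings <- sum(diff(c(FALSE, above)) == 1)
  expect_equal(openings, 2)
  # both reliability-critical regimes are present
  expect_gt(sum(areas > 0 & areas < 20), 0)
  expect_gt(sum(areas > 200), 0)
  # same seed, same video
  vid2 <- makeGlottisVideo(nFrames = 40, cycles = 2, seed = 4)
  expect_identical(frameMask(vid2[[17]]), frameMask(vid[[17]]))
})

test_that("simulated rater sets form a complete, reproducible grid", {
  pairs <- fixturePairs()[1:3]
  spec <- simulatedRaterSpec(nRaters = 4, nRounds = 3)
  set <- makeRaterSet(pairs, spec, seed = 6)
  expect_true(validObject(set))
  expect_equal(nRaters(set), 4L)
  expect_equal(nImages(set), 3L)
  expect_equal(nRounds(set), 3L)
  set2 <- makeRaterSet(pairs, spec, seed = 6)
  expect_identical(raterMask(set2, 3, 2, 1), raterMask(set, 3, 2, 1))
})

test_that("bias dominating round noise yields IaRR above IeRR", {
  pairs <- fixturePairs()[1:4]
  set <- makeRaterSet(pairs, simulatedRaterSpec(), seed = 2)
  rep <- reliabilityReport(set)
  expect_gt(rep$meanIaRR, rep$meanIeRR)
  # no bias and no noise: perfect agreement everywhere
  clean <- makeRaterSet(pairs,
                        simulatedRaterSpec(raterBias = rep(0, 6),
                                           noiseFraction = 0), seed = 1)
  r0 <- reliabilityReport(clean)
  expect_equal(r0$meanIaRR, 1)
  expect_equal(r0$meanIeRR, 1)
})

test_that("increasing round noise monotonically lowers IaRR", {
  pairs <- fixturePairs()[1:3]
  ia <- vapply(c(0.1, 0.25, 0.4, 0.6, 0.8), function(fr) {
    set <- makeRaterSet(pairs, simulatedRaterSpec(noiseFraction = fr),
                        seed = 3)
    mean(iarrVector(set))
  }, 0)
  expect_true(all(diff(ia) < 0))
})

test_that("corruption config YAML and mask-directory corruption round-trip", {
  cfg <- corruptionConfig(maxSpheres = 4L,
                          perlinThresholdRange = c(0.8, 0.9))
  p <- withr::local_tempfile(fileext = ".yaml")
  writeCorruptionConfig(cfg, p)
  back <- readCorruptionConfig(p)
  expect_equal(back@maxSpheres, 4L)
  expect_equal(back@perlinThresholdRange, c(0.8, 0.9))
  expect_equal(back@pApply, cfg@pApply)

  din <- withr::local_tempdir(); dout <- withr::local_tempdir()
  for (s in 1:2) {
    writeMaskPNG(frameMask(fixturePairs()[[s]]),
                 file.path(din, sprintf("m%d.png", s)))
  }
  man <- corruptMaskDir(din, dout, seed = 9, perMask = 2)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(file.path(dout, man$filename))))
  expect_true(all(man$true_iou >= 0 & man$true_iou <= 1))
  # applied steps survive as JSON
  steps <- jsonlite::fromJSON(man$applied_steps[1], simplifyVector = FALSE)
  expect_true(is.list(steps))
})
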