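test_that("crop and resize centres on the glottis and keeps masks binary", {
  fp <- fixturePairs()[[1]]
  out <- cropAndResize(fp, side = 48)
  expect_identical(dim(frameImage(out)), c(48L, 48L))
  expect_true(all(frameMask(out) %in% c(0, 1)))
  expect_gt(sum(frameMask(out)), 0)

  # non-square input: mask survives the square crop
  img <- matrix(runif(100 * 200, 0, 255), 100, 200)
  msk <- matrix(0, 100, 200); msk[40:60, 50:70] <- 1
  wide <- framePair(img, msk)
  out2 <- cropAndResize(wide, 224)
  expect_identical(dim(frameImage(out2)), c(224L, 224L))
  expect_true(all(frameMask(out2) %in% c(0, 1)))
  expect_gt(sum(frameMask(out2)), 0)

  # empty mask falls back to a centre crop
  empty <- framePair(img, matrix(0, 100, 200))
  expect_identical(dim(frameImage(cropAndResize(empty, 64))),
                   c(64L, 64L))
  tiny <- framePair(matrix(1, 4, 4), matrix(0, 4, 4))
  expect_error(cropAndResize(tiny), "too small")
})

test_that("intensity normalization maps [0,255] onto [-1,1]", {
  expect_equal(normalizeImage(0), -1)
  expect_equal(normalizeImage(255), 1)
  expect_equal(normalizeImage(127.5), 0)
})

test_that("composeInput assembles channels per scheme code", {
  fp <- fixturePairs()[[2]]
  deg <- degradedMask(degradeMask(fp, seed = 3))
  e <- normalizeImage(frameImage(fp))
  s <- deg * 2 - 1
  x <- composeInput(fp, deg, "see")
  expect_identical(x[, , 1], s)
  expect_identical(x[, , 2], e)
  expect_identical(x[, , 3], e)
  expect_identical(attr(x, "scheme"), "see")
  xs <- composeInput(fp, deg, "sss")
  expect_identical(xs[, , 1], xs[, , 2])
  expect_identical(xs[, , 2], xs[, , 3])
  xe <- composeInput(fp, deg, "eee")
  expect_identical(xe[, , 1], e)
  # mask channel re-binarized at 0 recovers the degraded mask exactly
  expect_identical(glottisQC:::.binarize(x[, , 1], threshold = 0), deg)
  expect_error(composeInput(fp, deg, "ses"),
               "eee, sss, see, sse, ees, ess")
  expect_true(all(x >= -1 & x <= 1))
})

test_that("balanced builder yields exactly flat bins and is replayable", {
  pairs <- fixturePairs()
  cfg <- corruptionConfig()
  man <- buildBalancedDataset(pairs, binSpec(20), perBin = 5, cfg,
                              seed = 31)
  expect_equal(nrow(man), 100)
  expect_true(all(table(factor(man$bin, 0:19)) == 5))
  # every row's recorded bin matches a from-scratch replay
  src <- vapply(pairs, sourceId, "")
  for (ri in seq(1, 100, by = 7)) {
    pair <- pairs[[match(man$source_id[ri], src)]]
    ds <- replaySample(pair, cfg, man$bin[ri], man$seed[ri])
    expect_equal(trueIoU(ds), man$true_iou[ri])
    expect_identical(binIndex(trueIoU(ds)), as.integer(man$bin[ri]))
  }
  # determinism of the whole manifest
  man2 <- buildBalancedDataset(pairs, binSpec(20), perBin = 5, cfg,
                               seed = 31)
  expect_identical(man, man2)
  expect_error(buildBalancedDataset(list(), binSpec(20), 5, cfg, seed = 1),
               "non-empty")
})

test_that("builder reports the starving bin when attempts run out", {
  pairs <- fixturePairs()[1:2]
  expect_error(
    buildBalancedDataset(pairs, binSpec(20), perBin = 5,
                         seed = 1, maxAttemptsPerBin = 2L),
    "bin \\d+ still holds")
})

test_that("stratified split has exact sizes and partitions the manifest", {
  pairs <- fixturePairs()
  man <- buildBalancedDataset(pairs, binSpec(20), perBin = 10, seed = 7)
  sp <- splitManifest(man, 0.05, seed = 8)
  expect_equal(nrow(sp$train), 190)
  expect_equal(nrow(sp$validation), 10)
  expect_setequal(c(sp$train$sample_id, sp$validation$sample_id),
                  man$sample_id)
  expect_length(intersect(sp$train$sample_id, sp$validation$sample_id), 0)
  # balance is preserved as far as arithmetic allows
  expect_true(all(table(factor(sp$validation$bin, 0:19)) <= 1))
})

test_that("manifest CSV round trip keeps the spec columns", {
  man <- buildBalancedDataset(fixturePairs(), binSpec(20), perBin = 2,
                              seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  writeManifest(man, p)
  back <- readManifest(p)
  expect_identical(names(back),
                   c("sample_id", "source_id", "mask_path", "true_iou",
                     "bin", "seed"))
  expect_equal(back$true_iou, man$true_iou)
  expect_equal(back$bin, man$bin)
})

test_that("regression tensors reproduce manifest targets and scheme", {
  pairs <- fixturePairs()
  man <- buildBalancedDataset(pairs, binSpec(20), perBin = 2, seed = 13)
  tens <- makeRegressionTensors(pairs, man, corruptionConfig(), "see")
  expect_identical(dim(tens$x), c(64L, 64L, 3L, 40L))
  expect_identical(tens$y, man$true_iou)
  expect_true(all(tens$x >= -1 & tens$x <= 1))
})
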