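test_that("traffic-light classes follow the thresholds, boundaries yellow", {
  expect_identical(classifyIoU(0.75), "green")
  expect_identical(classifyIoU(0.65), "yellow")
  expect_identical(classifyIoU(0.55), "red")
  expect_identical(classifyIoU(c(0.7, 0.6)), c("yellow", "yellow"))
  expect_error(classifyIoU(0.5, greenMin = 0.5, redMax = 0.6), "inverted")
  # monotone step function
  g <- seq(0, 1, by = 0.01)
  cls <- classifyIoU(g)
  lev <- c(red = 0, yellow = 1, green = 2)
  expect_true(all(diff(lev[cls]) >= 0))
  # lowering greenMin can only increase the green fraction
  f1 <- mean(classifyIoU(g, greenMin = 0.7) == "green")
  f2 <- mean(classifyIoU(g, greenMin = 0.6, redMax = 0.5) == "green")
  expect_gte(f2, f1)
})

test_that("video tracks preserve lengths and are consistent with classify", {
  vid <- makeGlottisVideo(nFrames = 12, cycles = 1, seed = 5)
  frames <- lapply(vid, frameImage)
  masks <- lapply(vid, frameMask)
  model <- buildModel("tiny", 64, seed = 1)   # untrained: plumbing check
  tracks <- trackVideo(frames, list(a = masks, b = masks), model,
                       videoId = "v1")
  expect_named(tracks, c("a", "b"))
  for (tr in tracks) {
    expect_length(tr, 12)
    expect_identical(frameClass(tr),
                     classifyIoU(predictedIoU(tr)))
  }
  # empty frame list gives an empty track
  empty <- trackVideo(list(), list(a = list()), model)
  expect_length(empty$a, 0)
  expect_error(trackVideo(frames, list(a = masks[1:3]), model),
               "3 masks for 12 frames")
})

test_that("rendered bar is one column per frame with a matching CSV", {
  iouSeq <- c(rep(0.9, 5), rep(0.65, 3), rep(0.3, 4))
  track <- new("TrafficLightTrack", iou = iouSeq,
               tlClass = classifyIoU(iouSeq), greenMin = 0.7,
               redMax = 0.6, videoId = "v", sourceId = "s",
               modelId = "m")
  png <- withr::local_tempfile(fileext = ".png")
  csv <- withr::local_tempfile(fileext = ".csv")
  bar <- renderBar(track, pngPath = png, csvPath = csv, height = 5)
  expect_identical(dim(bar$image), c(5L, 12L, 3L))
  expect_true(file.exists(png) && file.exists(csv))
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 12)
  expect_identical(tab$class, classifyIoU(tab$iou))
  expect_equal(unname(bar$fractions),
               c(5, 3, 4) / 12, tolerance = 1e-12)
  # all-green track renders a uniform bar
  g <- new("TrafficLightTrack", iou = rep(0.9, 4),
           tlClass = rep("green", 4), greenMin = 0.7, redMax = 0.6)
  bg <- renderBar(g)
  expect_equal(length(unique(as.vector(bg$image[1, , 1]))), 1)
  # class labels must stay consistent with the thresholds
  expect_error(new("TrafficLightTrack", iou = runif(100),
                   tlClass = classifyIoU(runif(100))),
               "inconsistent")
  # down-scaling caps the rendered width but not the CSV
  iouL <- runif(100)
  longOK <- new("TrafficLightTrack", iou = iouL,
                tlClass = classifyIoU(iouL), greenMin = 0.7, redMax = 0.6)
  bL <- renderBar(longOK, maxWidth = 40)
  expect_lte(dim(bL$image)[2], 50)
  expect_equal(nrow(bL$table), 100)
})
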