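test_that("model head is fixed and outputs live in (0,1)", {
  m <- buildModel("tiny", inputSide = 64, seed = 1)
  expect_identical(headLayers(m),
                   c("GlobalAveragePooling2D", "Dense(256, ReLU)",
                     "Dropout(0.1)", "Dense(1, sigmoid)"))
  expect_gt(nParameters(m), 1000)
  x <- array(runif(64 * 64 * 3 * 4, -1, 1), c(64, 64, 3, 4))
  p <- predictBatch(m, x)
  expect_length(p, 4)
  expect_true(all(p > 0 & p < 1))
  # same seed -> identical initial predictions
  m2 <- buildModel("tiny", inputSide = 64, seed = 1)
  expect_identical(predictBatch(m2, x), p)
  expect_error(buildModel("resnet50", 64), "registered backbones")
  expect_error(buildModel("tiny", 60), "divisible")
})

test_that("backbone registry accepts user recipes", {
  registerBackbone("tiny2", function(s) list(channels = c(4L, 8L)))
  expect_true("tiny2" %in% listBackbones())
  m <- buildModel("tiny2", inputSide = 16, seed = 3)
  expect_length(m@params$convW, 2)
  x <- array(0, c(16, 16, 3, 1))
  expect_true(predictBatch(m, x) > 0)
})

test_that("learning rate plateaus for 10 epochs then decays exponentially", {
  sp <- trainSpec("adam")
  expect_equal(sp$lr, 1e-3)
  expect_equal(trainSpec("sgd_momentum")$lr, 1e-2)
  expect_equal(lrAtEpoch(sp, 1), 1e-3)
  expect_equal(lrAtEpoch(sp, 10), 1e-3)
  expect_equal(lrAtEpoch(sp, 11), 1e-3 * exp(-0.1))
  expect_equal(lrAtEpoch(sp, 20), 1e-3 * exp(-1.0))
  one <- trainSpec("adam", decayMode = "one_time")
  expect_equal(lrAtEpoch(one, 20), 1e-3 * exp(-0.1))
  expect_error(trainSpec("adam", lr = -1), "lr must be")
})

test_that("analytic gradients match finite differences for every loss", {
  registerBackbone("gradcheck", function(s) list(channels = c(3L, 5L)))
  m <- buildModel("gradcheck", inputSide = 8, seed = 4)
  p <- m@params
  set.seed(8)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- c(0.3, 0.8)
  fb <- glottisQC:::.forwardBatch
  for (loss in c("bce", "mse", "mae")) {
    res <- fb(p, x, y, loss, wantGrad = TRUE)
    for (tensor in list(c("convW", 1), c("convW", 2), c("fcW1", NA),
                        c("fcW2", NA))) {
      nm <- tensor[1]; l <- suppressWarnings(as.integer(tensor[2]))
      getv <- function(pp) if (is.na(l)) pp[[nm]] else pp[[nm]][[l]]
      g <- if (nm == "convW") res$gradConvW[[l]] else
        res[[paste0("grad", toupper(substring(nm, 1, 1)),
                    substring(nm, 2))]]
      i <- sample(length(getv(p)), 1)
      eps <- 1e-6
      pp <- p; pm <- p
      if (is.na(l)) {
        pp[[nm]][i] <- pp[[nm]][i] + eps; pm[[nm]][i] <- pm[[nm]][i] - eps
      } else {
        pp[[nm]][[l]][i] <- pp[[nm]][[l]][i] + eps
        pm[[nm]][[l]][i] <- pm[[nm]][[l]][i] - eps
      }
      gn <- (fb(pp, x, y, loss)$loss - fb(pm, x, y, loss)$loss) / (2 * eps)
      expect_equal(g[i], gn, tolerance = 1e-4)
    }
  }
})

test_that("short training runs reduce loss and are exactly reproducible", {
  pairs <- fixturePairs()
  man <- buildBalancedDataset(pairs, binSpec(20), perBin = 6, seed = 17)
  tens <- makeRegressionTensors(pairs, man, corruptionConfig(), "see")
  sp <- trainSpec("adam", epochs = 4)
  m1 <- trainRegressor(buildModel("tiny", 64, seed = 2), tens$x, tens$y,
                       spec = sp, seed = 2)
  h <- trainHistory(m1)
  expect_equal(nrow(h), 4)
  expect_lt(h$trainLoss[4], h$trainLoss[1])
  m2 <- trainRegressor(buildModel("tiny", 64, seed = 2), tens$x, tens$y,
                       spec = sp, seed = 2)
  expect_equal(trainHistory(m2)$trainLoss, h$trainLoss, tolerance = 1e-6)
  expect_true(m1@trained)
  # predictIoU runs the full preprocess-compose-forward path
  fp <- pairs[[3]]
  pr <- predictIoU(m1, frameImage(fp), frameMask(fp), "see")
  expect_true(pr > 0 && pr < 1)
})

test_that("model comparison applies rank tests with Bonferroni correction", {
  set.seed(21)
  same <- rexp(30, 10)
  out <- compareModels(list(a = same, b = same, c = same + 1))
  expect_equal(out$bonferroniFactor, 3)
  ab <- out$pairwise[out$pairwise$group1 == "a" &
                       out$pairwise$group2 == "b", ]
  expect_false(ab$significant)                 # identical samples
  ac <- out$pairwise[out$pairwise$group1 == "a" &
                       out$pairwise$group2 == "c", ]
  expect_true(ac$significant)                  # clearly separated
  expect_true(all(out$pairwise$pAdjusted >= out$pairwise$p - 1e-12))
  expect_true(all(c("W", "p") %in% names(out$normality)))
  expect_equal(nrow(out$pairwise), 3)
})
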