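# small hand-built annotation grid: 2 raters, 2 images, 3 rounds on 4x4
.toyGrid <- function() {
  blk <- function(rs, cs) squareMask(4, rs, cs)
  list(
    list(  # rater 1
      list(blk(1:2, 1:2), blk(1:2, 1:2), blk(1:3, 1:2)),
      list(blk(3:4, 3:4), blk(3:4, 3:4), blk(3:4, 3:4))),
    list(  # rater 2
      list(blk(1:2, 1:3), blk(1:2, 1:2), blk(1:2, 1:2)),
      list(blk(2:4, 3:4), blk(3:4, 3:4), blk(3:4, 2:4))))
}

test_that("mean round mask averages pixelwise over rounds", {
  set <- raterAnnotationSet(.toyGrid())
  m <- meanRoundMask(set, 1, 1)
  expect_true(all(m %in% c(0, 1/3, 2/3, 1)))
  expect_equal(m[3, 1], 1/3)   # present in one of three rounds
  expect_equal(m[1, 1], 1)
  # identical rounds give the mask itself
  expect_identical(meanRoundMask(set, 1, 2), raterMask(set, 1, 2, 1))
  same <- raterAnnotationSet(list(list(list(squareMask(4, 1, 1),
                                            squareMask(4, 1, 1)))))
  expect_identical(meanRoundMask(same, 1, 1), squareMask(4, 1, 1))
})

test_that("IeRR matches the union-then-IoU brute-force oracle", {
  X <- .toyGrid()
  set <- raterAnnotationSet(X)
  u <- function(i, k) {
    (X[[i]][[k]][[1]] + X[[i]][[k]][[2]] + X[[i]][[k]][[3]] > 0) * 1
  }
  oracle <- mean(c(bruteIoU(u(1, 1), u(2, 1)), bruteIoU(u(1, 2), u(2, 2))))
  expect_equal(ierrPair(set, 1, 2), oracle)
  expect_equal(ierrPair(set, 1, 2), ierrPair(set, 2, 1))   # symmetry
  expect_error(ierrPair(set, 1, 1), "distinct")
  # Eq-threshold equivalence: 1(mean > 0) is the union over rounds
  expect_identical(glottisQC:::.binarize(meanRoundMask(set, 1, 1),
                                         threshold = 0), u(1, 1))
  # identical raters agree perfectly; disjoint raters not at all
  twin <- raterAnnotationSet(list(X[[1]], X[[1]]))
  expect_equal(ierrPair(twin, 1, 2), 1)
  disj <- raterAnnotationSet(list(
    list(list(squareMask(4, 1:2, 1:2))),
    list(list(squareMask(4, 3:4, 3:4)))))
  expect_equal(ierrPair(disj, 1, 2), 0)
  m <- ierrMatrix(set)
  expect_true(is.na(m[1, 1]) && is.na(m[2, 2]))
  expect_equal(m[1, 2], m[2, 1])
})

test_that("IaRR averages IoU over all round pairs, matching brute force", {
  X <- .toyGrid()
  set <- raterAnnotationSet(X)
  oracle <- mean(vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(p) {
    mean(c(bruteIoU(X[[1]][[1]][[p[1]]], X[[1]][[1]][[p[2]]]),
           bruteIoU(X[[1]][[2]][[p[1]]], X[[1]][[2]][[p[2]]])))
  }, 0))
  expect_equal(iarr(set, 1), oracle)
  # all rounds identical -> 1
  expect_equal(iarr(set, 1, images = 2), 1)
  # two disjoint rounds -> 0
  disj <- raterAnnotationSet(list(list(list(squareMask(4, 1:2, 1:2),
                                            squareMask(4, 3:4, 3:4)))))
  expect_equal(iarr(disj, 1), 0)
  expect_error(iarr(raterAnnotationSet(list(list(list(squareMask(4, 1, 1))))),
                    1), "2 rounds")
  expect_true(all(iarrVector(set) >= 0 & iarrVector(set) <= 1))
})

test_that("area strata separate unreliable small from reliable large areas", {
  # one-stratum case: stratum values equal global values
  pairs <- fixturePairs()[1:4]
  set <- makeRaterSet(pairs, simulatedRaterSpec(nRaters = 3, nRounds = 2,
                                                raterBias = c(-1, 0, 1)),
                      seed = 5)
  st <- stratifyByArea(set)
  big <- st[st$stratum == "(200,Inf)", ]
  if (nrow(st) == 1) {
    expect_equal(st$meanIeRR, mean(ierrMatrix(set), na.rm = TRUE))
    expect_equal(st$meanIaRR, mean(iarrVector(set)))
  }
  # constructed small vs large areas: small areas are less reliable
  mkimg <- function(area) {
    r <- floor(sqrt(area))
    squareMask(32, 8:(7 + r), 8:(7 + ceiling(area / r)))
  }
  gt <- list(framePair(matrix(128, 32, 32), mkimg(9)),
             framePair(matrix(128, 32, 32), mkimg(300)))
  set2 <- makeRaterSet(gt, simulatedRaterSpec(nRaters = 3, nRounds = 2,
                                              raterBias = c(-1, 0, 1),
                                              noiseFraction = 0.4),
                       seed = 6)
  st2 <- stratifyByArea(set2)
  small <- st2[st2$stratum == "(0,20)", ]
  large <- st2[st2$stratum == "(200,Inf)", ]
  if (nrow(small) && nrow(large)) {
    expect_lt(small$meanIeRR, large$meanIeRR)
  }
  # empty strata are absent, not zero
  expect_true(all(st2$nImages > 0))
})

test_that("agreement decays from the glottis centre towards the boundary", {
  pairs <- fixturePairs()[1:3]
  # boundary-only perturbations: identical centre, fuzzy edge
  set <- makeRaterSet(pairs, simulatedRaterSpec(nRaters = 3, nRounds = 2,
                                                raterBias = c(0, 0, 0),
                                                noiseFraction = 0.5),
                      seed = 9)
  prof <- agreementVsDistance(set, nRings = 5)
  expect_true(all(prof$agreement >= 0 & prof$agreement <= 1, na.rm = TRUE))
  com <- prof[prof$metric == "com", ]
  expect_equal(com$agreement[1], 1, tolerance = 1e-6)   # innermost ring
  edge <- prof[prof$metric == "edge", ]
  boundary <- edge$agreement[which.min(abs(edge$mid))]
  expect_lt(boundary, 1)
  # identical masks everywhere -> agreement 1 in every ring
  same <- makeRaterSet(pairs, simulatedRaterSpec(nRaters = 2, nRounds = 2,
                                                 raterBias = c(0, 0),
                                                 noiseFraction = 0),
                       seed = 1)
  p2 <- agreementVsDistance(same, nRings = 4)
  expect_true(all(abs(p2$agreement - 1) < 1e-12, na.rm = TRUE))
})

test_that("rater tree IO round-trips through the directory layout", {
  pairs <- fixturePairs()[1:2]
  set <- makeRaterSet(pairs, simulatedRaterSpec(nRaters = 2, nRounds = 2),
                      seed = 3)
  d <- withr::local_tempdir()
  writeRaterTree(set, d)
  back <- readRaterTree(d)
  expect_equal(nRaters(back), 2L)
  expect_equal(nRounds(back), 2L)
  expect_identical(raterMask(back, 2, 1, 2), raterMask(set, 2, 1, 2))
  expect_equal(ierrPair(back, 1, 2), ierrPair(set, 1, 2))
})
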