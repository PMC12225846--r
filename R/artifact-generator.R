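#' @include AllClasses.R
NULL

# 3x3 cross structuring element shared by all morphology steps
.cross3 <- function() EBImage::makeBrush(3L, shape = "diamond")

# evaluate `code` under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

.asMask <- function(x) {
  m <- matrix(as.double(x > 0.5), nrow(x), ncol(x))
  m
}

# zero-padded shift: positive di moves content down (row index grows)
.shift2 <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + di):min(nr, nr + di)
  cs <- max(1, 1 + dj):min(nc, nc + dj)
  out[rs, cs] <- m[rs - di, cs - dj]
  out
}

# Sobel gradient magnitude via explicit shifts (replicate-free, zero-padded;
# exact on binary masks and immune to FFT wrap-around)
.sobelMagnitude <- function(m) {
  gx <- (.shift2(m, -1, -1) + 2 * .shift2(m, 0, -1) + .shift2(m, 1, -1)) -
        (.shift2(m, -1,  1) + 2 * .shift2(m, 0,  1) + .shift2(m, 1,  1))
  gy <- (.shift2(m, -1, -1) + 2 * .shift2(m, -1, 0) + .shift2(m, -1, 1)) -
        (.shift2(m,  1, -1) + 2 * .shift2(m,  1, 0) + .shift2(m,  1, 1))
  sqrt(gx^2 + gy^2)
}

#' Build a corruption configuration
#'
#' Defaults give corruptions whose IoU-vs-ground-truth spans most of \[0, 1\]
#' on typical glottis masks: morphology iterations U\{1..5\} with a fair
#' erode/dilate coin, border-flip probability 0.5, up to 5 discs of radius
#' 1-3 px within 10 px of the glottis, and Perlin blobs with U\{2..8\}
#' lattice periods binarized at a U\[0.85, 0.97\] quantile (union mode).
#'
#' @param pApply per-step application probabilities, named
#'   \code{scaling}, \code{borderFuzz}, \code{smallArtifacts},
#'   \code{largeArtifacts}.
#' @param scalingIterationsRange,sphereRadiusRange,perlinPeriodsRange
#'   inclusive integer ranges.
#' @param edgeFlipProbability,perlinThresholdRange,perlinMode,maxSpheres,sphereProximity
#'   see [CorruptionConfig-class].
#' @return A [CorruptionConfig-class] object.
#' @export
corruptionConfig <- function(pApply = c(scaling = 0.5, borderFuzz = 0.5,
                                        smallArtifacts = 0.5,
                                        largeArtifacts = 0.5),
                             scalingIterationsRange = c(1L, 5L),
                             edgeFlipProbability = 0.5,
                             maxSpheres = 5L,
                             sphereRadiusRange = c(1L, 3L),
                             sphereProximity = 10L,
                             perlinPeriodsRange = c(2L, 8L),
                             perlinThresholdRange = c(0.85, 0.97),
                             perlinMode = "union") {
  new("CorruptionConfig",
      pApply = pApply,
      scalingIterationsRange = as.integer(scalingIterationsRange),
      edgeFlipProbability = edgeFlipProbability,
      maxSpheres = as.integer(maxSpheres),
      sphereRadiusRange = as.integer(sphereRadiusRange),
      sphereProximity = as.integer(sphereProximity),
      perlinPeriodsRange = as.integer(perlinPeriodsRange),
      perlinThresholdRange = perlinThresholdRange,
      perlinMode = perlinMode)
}

#' Uniform mask scaling by iterated binary morphology
#'
#' Erodes or dilates the mask with a 3x3 cross structuring element,
#' \code{iterations} times, mimicking systematically too-small or too-large
#' segmentations.
#'
#' @param m binary matrix.
#' @param iterations number of morphology passes (>= 1).
#' @param mode \code{"erode"} or \code{"dilate"}.
#' @return binary matrix.
#' @export
applyUniformScaling <- function(m, iterations, mode = c("erode", "dilate")) {
  mode <- match.arg(mode)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  k <- .cross3()
  f <- if (mode == "erode") EBImage::erode else EBImage::dilate
  out <- m
  for (it in seq_len(iterations)) out <- f(out, k)
  .asMask(as.matrix(out))
}

# edge band: binarized Sobel magnitude, dilated once with the cross
.edgeBand <- function(m) {
  band0 <- .asMask(.sobelMagnitude(m) > 0)
  if (!any(band0 > 0)) return(band0)
  .asMask(as.matrix(EBImage::dilate(band0, .cross3())))
}

#' Border fuzz: randomize pixels along the mask boundary
#'
#' Detects the mask edge with a Sobel filter, dilates the binarized edge
#' once, and then independently sets every pixel of that band to foreground
#' with probability \code{flipP} (background otherwise). Pixels outside the
#' band are untouched. Emulates rater uncertainty at the glottal border.
#' Draws from the current R RNG stream.
#'
#' @param m binary matrix.
#' @param flipP probability in \[0, 1\] that a band pixel becomes foreground.
#' @return binary matrix.
#' @export
applyBorderFuzz <- function(m, flipP = 0.5) {
  if (flipP < 0 || flipP > 1) stop("flipP must lie in [0, 1]")
  band <- .edgeBand(m)
  idx <- which(band > 0)
  if (!length(idx)) return(.asMask(m))
  out <- .asMask(m)
  out[idx] <- as.double(stats::runif(length(idx)) < flipP)
  out
}

#' Small segmentation artifacts: random discs near the glottis
#'
#' Unions 1..\code{maxSpheres} discs (radius drawn uniformly from
#' \code{radiusRange}) onto the mask. Disc centres are sampled uniformly
#' from the background at distance at most \code{proximity - radius} from
#' the original foreground, so every added pixel stays within
#' \code{proximity} pixels of the glottis. An empty mask is returned
#' unchanged (there is no glottis to be close to). Draws from the current R
#' RNG stream.
#'
#' @param m binary matrix.
#' @param maxSpheres maximum disc count.
#' @param radiusRange inclusive integer radius range in pixels.
#' @param proximity maximum distance (pixels) of added pixels from the
#'   original foreground.
#' @return binary matrix.
#' @export
applySmallArtifacts <- function(m, maxSpheres = 5L, radiusRange = c(1L, 3L),
                                proximity = 10L) {
  m <- .asMask(m)
  if (!any(m > 0)) return(m)
  d <- .distToForeground(m)
  n <- sample.int(maxSpheres, 1L)
  out <- m
  drawn <- list()
  for (s in seq_len(n)) {
    r <- sample(seq.int(radiusRange[1], radiusRange[2]), 1L)
    ok <- which(d > 0 & d <= max(1, proximity - r))
    if (!length(ok)) next
    ctr <- ok[sample.int(length(ok), 1L)]
    ci <- (ctr - 1L) %% nrow(m) + 1L
    cj <- (ctr - 1L) %/% nrow(m) + 1L
    out <- .stampDisc(out, ci, cj, r)
    drawn[[length(drawn) + 1L]] <- c(row = ci, col = cj, radius = r)
  }
  attr(out, "spheres") <- drawn
  out
}

# Euclidean distance of every pixel to the nearest foreground pixel
.distToForeground <- function(m) {
  as.matrix(EBImage::distmap(1 - m, metric = "euclidean"))
}

.stampDisc <- function(m, ci, cj, r) {
  rs <- max(1L, ci - r):min(nrow(m), ci + r)
  cs <- max(1L, cj - r):min(ncol(m), cj + r)
  for (j in cs) {
    dj2 <- (j - cj)^2
    within <- rs[(rs - ci)^2 + dj2 <= r^2]
    m[within, j] <- 1
  }
  m
}

#' Large segmentation artifacts: thresholded Perlin-noise blobs
#'
#' Generates a coherent Perlin-noise field over the mask grid (padded so
#' each side is divisible by \code{periods}, then cropped) and keeps the
#' fraction \code{1 - thresholdQuantile} of highest-valued pixels as blob
#' foreground. The blobs are combined with the mask by union (default;
#' spurious extra area) or symmetric difference (\code{mode = "xor"}).
#' Draws from the current R RNG stream.
#'
#' @param m binary matrix.
#' @param periods Perlin lattice periods per axis.
#' @param thresholdQuantile quantile in \[0, 1\]; 1 adds nothing, 0 floods
#'   the frame.
#' @param mode \code{"union"} or \code{"xor"}.
#' @return binary matrix.
#' @export
applyLargeArtifacts <- function(m, periods, thresholdQuantile,
                                mode = c("union", "xor")) {
  mode <- match.arg(mode)
  if (thresholdQuantile < 0 || thresholdQuantile > 1) {
    stop("thresholdQuantile must lie in [0, 1]")
  }
  nr <- nrow(m); nc <- ncol(m)
  pr <- as.integer(ceiling(nr / periods) * periods)
  pc <- as.integer(ceiling(nc / periods) * periods)
  field <- perlinNoise(pr, pc, periods)[seq_len(nr), seq_len(nc)]
  # rank-based threshold: exactly the top (1 - q) fraction becomes blob
  keep <- rank(as.vector(field), ties.method = "first") >
    thresholdQuantile * length(field)
  blob <- matrix(as.double(keep), nr, nc)
  m <- .asMask(m)
  if (mode == "union") .asMask(m + blob > 0) else .asMask(abs(m - blob))
}

#' Degrade a ground-truth mask and label it with its exact IoU
#'
#' Applies the four corruption steps in fixed order -- uniform scaling,
#' border fuzz, small disc artifacts, large Perlin artifacts -- each
#' independently with its configured application probability and with
#' hyperparameters drawn from the configured ranges. The result is labelled
#' with the IoU against the untouched original and with the ordered record
#' of applied steps, and is bit-identical when replayed with the same
#' \code{(cfg, seed)}.
#'
#' @param x a [FramePair-class] or a binary matrix.
#' @param cfg a [CorruptionConfig-class].
#' @param seed integer seed for this draw.
#' @param ensureApplied if TRUE, the per-step Bernoulli draws are resampled
#'   until at least one step applies (used by the balanced-dataset sampler,
#'   where an untouched mask would pile every draw into the top bin).
#' @return A [DegradedSample-class].
#' @examples
#' fp <- makeGlottisPair(glottisPhantomSpec(side = 64), seed = 1)
#' ds <- degradeMask(fp, corruptionConfig(), seed = 7)
#' trueIoU(ds)
#' @export
degradeMask <- function(x, cfg = corruptionConfig(), seed,
                        ensureApplied = FALSE) {
  m0 <- if (is(x, "FramePair")) frameMask(x) else .asMask(x)
  .withSeed(as.integer(seed), {
    apply4 <- stats::runif(4) < cfg@pApply
    if (ensureApplied) {
      while (!any(apply4)) apply4 <- stats::runif(4) < cfg@pApply
    }
    m <- m0
    steps <- list()
    if (apply4[1]) {
      iters <- sample(seq.int(cfg@scalingIterationsRange[1],
                              cfg@scalingIterationsRange[2]), 1L)
      mode <- if (stats::runif(1) < 0.5) "erode" else "dilate"
      m <- applyUniformScaling(m, iters, mode)
      steps <- c(steps, list(list(step = "scaling",
                                  params = list(iterations = iters,
                                                mode = mode))))
    }
    if (apply4[2]) {
      m <- applyBorderFuzz(m, cfg@edgeFlipProbability)
      steps <- c(steps, list(list(step = "borderFuzz",
                                  params = list(flipP = cfg@edgeFlipProbability))))
    }
    if (apply4[3]) {
      m2 <- applySmallArtifacts(m, cfg@maxSpheres, cfg@sphereRadiusRange,
                                cfg@sphereProximity)
      steps <- c(steps, list(list(step = "smallArtifacts",
                                  params = list(spheres = attr(m2, "spheres")))))
      attr(m2, "spheres") <- NULL
      m <- m2
    }
    if (apply4[4]) {
      periods <- sample(seq.int(cfg@perlinPeriodsRange[1],
                                cfg@perlinPeriodsRange[2]), 1L)
      q <- stats::runif(1, cfg@perlinThresholdRange[1],
                        cfg@perlinThresholdRange[2])
      m <- applyLargeArtifacts(m, periods, q, cfg@perlinMode)
      steps <- c(steps, list(list(step = "largeArtifacts",
                                  params = list(periods = periods,
                                                thresholdQuantile = q,
                                                mode = cfg@perlinMode))))
    }
    new("DegradedSample", original = m0, degraded = .asMask(m),
        trueIoU = iou(m0, m), appliedSteps = steps,
        seed = as.integer(seed))
  })
}
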