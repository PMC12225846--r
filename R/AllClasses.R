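#' @import methods
NULL

# Binary masks and grayscale frames are plain base matrices throughout:
# masks hold exactly 0/1 (integer or double), images hold [0, 255].
# The S4 layer wraps the composite objects that travel between modules.

.checkMask <- function(m, what = "mask") {
  if (!is.matrix(m)) return(sprintf("%s must be a matrix", what))
  if (length(m) == 0L) return(sprintf("%s must be non-empty", what))
  v <- unique(as.vector(m))
  if (!all(v %in% c(0, 1))) {
    return(sprintf("%s values must be exactly 0 or 1", what))
  }
  NULL
}

#' FramePair: one endoscopy frame with its binary glottal-area mask
#'
#' Couples a grayscale endoscopy image (values in \[0, 255\]) with a binary
#' segmentation mask of identical dimensions. This is the atomic unit every
#' other component consumes: the artifact generator corrupts its mask, the
#' dataset builder crops/resizes/composes it, and the regressor predicts the
#' IoU of an arbitrary candidate mask against its frame.
#'
#' @slot image numeric matrix, grayscale intensities in \[0, 255\].
#' @slot mask numeric matrix of 0/1, same dimensions as \code{image}.
#' @slot sourceId character scalar identifying the frame's origin.
#' @export
setClass("FramePair",
  representation(image = "matrix", mask = "matrix", sourceId = "character"),
  prototype(sourceId = NA_character_))

setValidity("FramePair", function(object) {
  msgs <- character()
  if (!is.numeric(object@image)) msgs <- c(msgs, "image must be numeric")
  if (any(object@image < 0 | object@image > 255)) {
    msgs <- c(msgs, "image values must lie in [0, 255]")
  }
  mm <- .checkMask(object@mask)
  if (!is.null(mm)) msgs <- c(msgs, mm)
  if (!identical(dim(object@image), dim(object@mask))) {
    msgs <- c(msgs, sprintf(
      "image (%s) and mask (%s) dimensions differ",
      paste(dim(object@image), collapse = "x"),
      paste(dim(object@mask), collapse = "x")))
  }
  if (length(msgs)) msgs else TRUE
})

#' CorruptionConfig: hyperparameter ranges for the mask corruption pipeline
#'
#' Controls the four stochastic corruption operators applied (each with its
#' own application probability, in fixed order) by [degradeMask()]: uniform
#' morphological scaling, Sobel border fuzz, small disc artifacts, and large
#' Perlin-noise artifacts. Step hyperparameters are drawn uniformly from the
#' configured ranges at application time.
#'
#' @slot pApply named numeric(4), per-step application probability for
#'   \code{scaling}, \code{borderFuzz}, \code{smallArtifacts},
#'   \code{largeArtifacts}.
#' @slot scalingIterationsRange integer(2), inclusive range of morphology
#'   iterations.
#' @slot edgeFlipProbability numeric, probability that an edge-band pixel is
#'   set to foreground.
#' @slot maxSpheres integer, maximum number of disc artifacts.
#' @slot sphereRadiusRange integer(2), inclusive disc radius range (pixels).
#' @slot sphereProximity integer, max distance (pixels) of disc pixels from
#'   the original foreground.
#' @slot perlinPeriodsRange integer(2), inclusive range of Perlin lattice
#'   periods per axis.
#' @slot perlinThresholdRange numeric(2), range of the quantile above which
#'   Perlin noise becomes foreground (lower quantile = larger blobs).
#' @slot perlinMode character, \code{"union"} (noise adds spurious area,
#'   default) or \code{"xor"}.
#' @export
setClass("CorruptionConfig",
  representation(
    pApply = "numeric",
    scalingIterationsRange = "integer",
    edgeFlipProbability = "numeric",
    maxSpheres = "integer",
    sphereRadiusRange = "integer",
    sphereProximity = "integer",
    perlinPeriodsRange = "integer",
    perlinThresholdRange = "numeric",
    perlinMode = "character"))

setValidity("CorruptionConfig", function(object) {
  msgs <- character()
  p <- object@pApply
  steps <- c("scaling", "borderFuzz", "smallArtifacts", "largeArtifacts")
  if (length(p) != 4L || !identical(names(p), steps)) {
    msgs <- c(msgs, sprintf("pApply must be named numeric(4): %s",
                            paste(steps, collapse = ", ")))
  } else if (any(p < 0 | p > 1)) {
    msgs <- c(msgs, "pApply values must lie in [0, 1]")
  }
  rng2 <- function(x, nm, lo = 1L) {
    if (length(x) != 2L || x[1] > x[2] || x[1] < lo) {
      sprintf("%s must be an ordered range with lower bound >= %d", nm, lo)
    } else NULL
  }
  msgs <- c(msgs,
    rng2(object@scalingIterationsRange, "scalingIterationsRange"),
    rng2(object@sphereRadiusRange, "sphereRadiusRange"),
    rng2(object@perlinPeriodsRange, "perlinPeriodsRange"))
  if (object@edgeFlipProbability < 0 || object@edgeFlipProbability > 1) {
    msgs <- c(msgs, "edgeFlipProbability must lie in [0, 1]")
  }
  tr <- object@perlinThresholdRange
  if (length(tr) != 2L || tr[1] > tr[2] || tr[1] < 0 || tr[2] > 1) {
    msgs <- c(msgs, "perlinThresholdRange must be an ordered range in [0, 1]")
  }
  if (object@maxSpheres < 1L) msgs <- c(msgs, "maxSpheres must be >= 1")
  if (object@sphereProximity < 1L) msgs <- c(msgs, "sphereProximity must be >= 1")
  if (!object@perlinMode %in% c("union", "xor")) {
    msgs <- c(msgs, "perlinMode must be 'union' or 'xor'")
  }
  if (length(msgs)) msgs else TRUE
})

#' DegradedSample: a corrupted mask labelled with its exact IoU
#'
#' Produced by [degradeMask()]: the untouched original mask, the degraded
#' mask, the true IoU between them, the ordered record of applied corruption
#' steps with their sampled hyperparameters, and the seed that makes the
#' whole draw replayable.
#'
#' @slot original,degraded numeric 0/1 matrices of equal dimensions.
#' @slot trueIoU numeric in \[0, 1\], equal to \code{iou(original, degraded)}.
#' @slot appliedSteps list of \code{list(step =, params =)} in application
#'   order.
#' @slot seed integer seed that reproduces the draw for a fixed config.
#' @export
setClass("DegradedSample",
  representation(original = "matrix", degraded = "matrix",
                 trueIoU = "numeric", appliedSteps = "list",
                 seed = "integer"))

setValidity("DegradedSample", function(object) {
  msgs <- c(.checkMask(object@original, "original"),
            .checkMask(object@degraded, "degraded"))
  if (!identical(dim(object@original), dim(object@degraded))) {
    msgs <- c(msgs, "original and degraded dimensions differ")
  }
  if (object@trueIoU < 0 || object@trueIoU > 1) {
    msgs <- c(msgs, "trueIoU must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' RaterAnnotationSet: multi-rater, multi-round binary annotations
#'
#' A complete grid of binary masks indexed by (rater i, image k, round r),
#' as produced by repeated manual annotation of the same image set. Input to
#' the inter-rater (IeRR) and intra-rater (IaRR) reliability analyses.
#'
#' @slot masks list of length \code{nRaters}; element i is a list of length
#'   \code{nImages}; element (i, k) is a list of \code{nRounds} binary
#'   matrices sharing that image's dimensions.
#' @slot nRaters,nImages,nRounds positive integers.
#' @export
setClass("RaterAnnotationSet",
  representation(masks = "list", nRaters = "integer", nImages = "integer",
                 nRounds = "integer"))

setValidity("RaterAnnotationSet", function(object) {
  N <- object@nRaters; K <- object@nImages; R <- object@nRounds
  if (N < 1L || K < 1L || R < 1L) return("nRaters, nImages, nRounds must be >= 1")
  if (length(object@masks) != N) return("masks must have one element per rater")
  for (i in seq_len(N)) {
    if (length(object@masks[[i]]) != K) {
      return(sprintf("rater %d must have %d images", i, K))
    }
    for (k in seq_len(K)) {
      rounds <- object@masks[[i]][[k]]
      if (length(rounds) != R) {
        return(sprintf("rater %d image %d must have %d rounds", i, k, R))
      }
      d0 <- dim(object@masks[[1L]][[k]][[1L]])
      for (r in seq_len(R)) {
        m <- rounds[[r]]
        err <- .checkMask(m, sprintf("mask (%d,%d,%d)", i, k, r))
        if (!is.null(err)) return(err)
        if (!identical(dim(m), d0)) {
          return(sprintf("mask (%d,%d,%d) dimensions differ within image %d",
                         i, k, r, k))
        }
      }
    }
  }
  TRUE
})

#' IoURegressor: a convolutional IoU regression model
#'
#' A feed-forward network that maps a 3-channel composed input (image and/or
#' mask channels, normalized to \[-1, 1\]) to a predicted IoU in (0, 1). The
#' backbone (a stack of 3x3-conv/ReLU/max-pool blocks for the bundled
#' \code{"tiny"} backbone) feeds the fixed head: global average pooling,
#' dense 256 + ReLU, dropout 0.1, dense 1 + sigmoid.
#'
#' @slot backbone character, registered backbone name.
#' @slot inputSide integer, expected square input side in pixels.
#' @slot params list of weight matrices/vectors.
#' @slot layers character vector describing the layer sequence.
#' @slot loss character, training loss ("bce", "mse" or "mae").
#' @slot history data.frame of per-epoch train/validation loss (empty until
#'   trained).
#' @slot trained logical.
#' @export
setClass("IoURegressor",
  representation(backbone = "character", inputSide = "integer",
                 params = "list", layers = "character", loss = "character",
                 history = "data.frame", trained = "logical"),
  prototype(loss = "bce", trained = FALSE, history = data.frame()))

#' TrafficLightTrack: per-frame predicted IoU with traffic-light classes
#'
#' The per-frame quality report for one video under one segmentation source:
#' predicted IoU values together with their green/yellow/red class under the
#' configured thresholds.
#'
#' @slot iou numeric vector of predicted IoU, one per frame.
#' @slot class character vector in \{"green","yellow","red"\}, same length.
#' @slot greenMin,redMax numeric thresholds (green above \code{greenMin},
#'   red below \code{redMax}, yellow otherwise, boundaries inclusive to
#'   yellow).
#' @slot videoId,sourceId,modelId character labels.
#' @export
setClass("TrafficLightTrack",
  representation(iou = "numeric", tlClass = "character",
                 greenMin = "numeric", redMax = "numeric",
                 videoId = "character", sourceId = "character",
                 modelId = "character"),
  prototype(videoId = NA_character_, sourceId = NA_character_,
            modelId = NA_character_, greenMin = 0.7, redMax = 0.6))

setValidity("TrafficLightTrack", function(object) {
  msgs <- character()
  if (length(object@iou) != length(object@tlClass)) {
    msgs <- c(msgs, "iou and class must have equal length")
  }
  if (object@redMax > object@greenMin) {
    msgs <- c(msgs, "redMax must be <= greenMin")
  }
  expect <- classifyIoU(object@iou, greenMin = object@greenMin,
                        redMax = object@redMax)
  if (!identical(expect, object@tlClass)) {
    msgs <- c(msgs, "class labels inconsistent with thresholds")
  }
  if (length(msgs)) msgs else TRUE
})

#' GlottisPhantomSpec: parameters of the synthetic glottis frame generator
#'
#' Describes a spindle-shaped dark glottal gap (pointed ends along the main
#' axis, widest at the centre) on a brighter textured background, with a
#' bright rim just outside the gap mimicking the vocal-fold edges.
#'
#' @slot side integer, square frame side in pixels.
#' @slot length numeric, spindle length in pixels along its main axis.
#' @slot maxWidth numeric, spindle width at the centre; 0 gives an empty
#'   mask (closed glottis).
#' @slot orientation numeric, main-axis angle in radians.
#' @slot centroidJitter numeric, max uniform jitter of the spindle centre.
#' @slot contrast numeric (> 0), intensity drop inside the glottal gap.
#' @slot textureAmplitude numeric, amplitude of the smoothed background
#'   noise texture.
#' @slot sizeJitter numeric in \[0, 1): per-draw spindle length and width
#'   are scaled by independent U(1 - sizeJitter, 1) factors, so glottis
#'   size varies between frames as it does between patients.
#' @slot orientationJitter numeric, max uniform deviation (radians) of the
#'   main axis per draw.
#' @export
setClass("GlottisPhantomSpec",
  representation(side = "integer", length = "numeric", maxWidth = "numeric",
                 orientation = "numeric", centroidJitter = "numeric",
                 contrast = "numeric", textureAmplitude = "numeric",
                 sizeJitter = "numeric", orientationJitter = "numeric"))

setValidity("GlottisPhantomSpec", function(object) {
  msgs <- character()
  if (object@side < 16L) msgs <- c(msgs, "side must be >= 16")
  if (object@contrast <= 0) msgs <- c(msgs, "contrast must be > 0")
  if (object@maxWidth < 0) msgs <- c(msgs, "maxWidth must be >= 0")
  if (object@sizeJitter < 0 || object@sizeJitter >= 1) {
    msgs <- c(msgs, "sizeJitter must lie in [0, 1)")
  }
  half <- sqrt((object@length / 2)^2 + (object@maxWidth / 2)^2)
  if (half + object@centroidJitter > object@side / 2) {
    msgs <- c(msgs, "spindle (plus jitter) must fit inside the frame")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimulatedRaterSpec: parameters of the simulated annotation study
#'
#' Simulated raters re-annotate the same images over several rounds. Each
#' rater carries a systematic bias (a dilate/erode tendency, constant across
#' rounds) and each round adds independent border fuzz. Bias drives
#' between-rater disagreement; fuzz drives within-rater round-to-round
#' variation.
#'
#' @slot nRaters,nRounds positive integers.
#' @slot raterBias numeric vector of length \code{nRaters}; signed
#'   morphology iterations (positive = dilate, negative = erode, 0 = none).
#' @slot noiseFlipP numeric in \[0, 1\]; probability that an affected
#'   edge-band pixel is set to foreground.
#' @slot noiseFraction numeric in \[0, 1\]; fraction of the edge band
#'   re-randomized independently in each round -- the intra-rater noise
#'   level (0 disables round noise entirely).
#' @export
setClass("SimulatedRaterSpec",
  representation(nRaters = "integer", nRounds = "integer",
                 raterBias = "numeric", noiseFlipP = "numeric",
                 noiseFraction = "numeric"))

setValidity("SimulatedRaterSpec", function(object) {
  msgs <- character()
  if (object@nRaters < 1L || object@nRounds < 1L) {
    msgs <- c(msgs, "nRaters and nRounds must be >= 1")
  }
  if (length(object@raterBias) != object@nRaters) {
    msgs <- c(msgs, "raterBias must have one entry per rater")
  }
  if (object@noiseFlipP < 0 || object@noiseFlipP > 1) {
    msgs <- c(msgs, "noiseFlipP must lie in [0, 1]")
  }
  if (object@noiseFraction < 0 || object@noiseFraction > 1) {
    msgs <- c(msgs, "noiseFraction must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})
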