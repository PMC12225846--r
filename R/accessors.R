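#' @include AllGenerics.R
NULL

#' Construct a FramePair
#'
#' @param image numeric matrix with values in \[0, 255\] (an RGB array is
#'   converted to grayscale by the luma transform first).
#' @param mask binary matrix (0/1) of the same dimensions; anything > 0.5 is
#'   treated as foreground.
#' @param sourceId optional identifier.
#' @return A [FramePair-class] object.
#' @examples
#' fp <- framePair(matrix(128, 16, 16), matrix(0, 16, 16))
#' dim(frameMask(fp))
#' @export
framePair <- function(image, mask, sourceId = NA_character_) {
  if (length(dim(image)) == 3L) image <- rgbToGray(image)
  storage.mode(image) <- "double"
  mask <- .binarize(mask)
  new("FramePair", image = image, mask = mask,
      sourceId = as.character(sourceId))
}

# coerce any numeric mask-like matrix to strict 0/1 double
.binarize <- function(m, threshold = 0.5) {
  m <- matrix(as.double(m > threshold), nrow(m), ncol(m))
  m
}

#' Convert an RGB array to a grayscale matrix
#'
#' Rec. 601 luma weights; values keep the input scale.
#' @param x H x W x 3 numeric array.
#' @return H x W numeric matrix.
#' @export
rgbToGray <- function(x) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] >= 3L)
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

#' @describeIn framePair the grayscale image matrix
#' @param x a \code{FramePair}
#' @export
setMethod("frameImage", "FramePair", function(x) x@image)

#' @describeIn framePair the binary mask matrix
#' @export
setMethod("frameMask", "FramePair", function(x) x@mask)

#' @describeIn framePair the source identifier
#' @export
setMethod("sourceId", "FramePair", function(x) x@sourceId)

setMethod("show", "FramePair", function(object) {
  cat(sprintf("FramePair [%dx%d] source=%s mask area=%d px\n",
              nrow(object@image), ncol(object@image),
              object@sourceId, as.integer(sum(object@mask))))
})

#' @describeIn degradeMask original (ground-truth) mask of a sample
#' @param x a \code{DegradedSample}
#' @export
setMethod("originalMask", "DegradedSample", function(x) x@original)

#' @describeIn degradeMask degraded mask of a sample
#' @export
setMethod("degradedMask", "DegradedSample", function(x) x@degraded)

#' @describeIn degradeMask stored true IoU of a sample
#' @export
setMethod("trueIoU", "DegradedSample", function(x) x@trueIoU)

#' @describeIn degradeMask ordered list of applied steps with sampled
#'   hyperparameters
#' @export
setMethod("appliedSteps", "DegradedSample", function(x) x@appliedSteps)

setMethod("show", "DegradedSample", function(object) {
  steps <- vapply(object@appliedSteps, `[[`, "", "step")
  cat(sprintf("DegradedSample [%dx%d] trueIoU=%.4f steps=[%s] seed=%d\n",
              nrow(object@original), ncol(object@original), object@trueIoU,
              paste(steps, collapse = ", "), object@seed))
})

#' @describeIn raterAnnotationSet number of raters
#' @param x a \code{RaterAnnotationSet}
#' @export
setMethod("nRaters", "RaterAnnotationSet", function(x) x@nRaters)

#' @describeIn raterAnnotationSet number of images
#' @export
setMethod("nImages", "RaterAnnotationSet", function(x) x@nImages)

#' @describeIn raterAnnotationSet number of annotation rounds
#' @export
setMethod("nRounds", "RaterAnnotationSet", function(x) x@nRounds)

#' @describeIn raterAnnotationSet the binary mask of rater \code{i}, image
#'   \code{k}, round \code{r}
#' @param i,k,r rater, image and round index (1-based)
#' @export
setMethod("raterMask", "RaterAnnotationSet",
          function(x, i, k, r) x@masks[[i]][[k]][[r]])

setMethod("show", "RaterAnnotationSet", function(object) {
  cat(sprintf("RaterAnnotationSet: %d raters x %d images x %d rounds\n",
              object@nRaters, object@nImages, object@nRounds))
})

#' Assemble a RaterAnnotationSet from a nested mask list
#'
#' @param masks list indexed \code{[[rater]][[image]][[round]]} of binary
#'   matrices; the grid must be complete.
#' @return A [RaterAnnotationSet-class].
#' @export
raterAnnotationSet <- function(masks) {
  N <- length(masks)
  K <- if (N) length(masks[[1L]]) else 0L
  R <- if (K) length(masks[[1L]][[1L]]) else 0L
  masks <- lapply(masks, function(byImage) {
    lapply(byImage, function(rounds) lapply(rounds, .binarize))
  })
  new("RaterAnnotationSet", masks = masks, nRaters = as.integer(N),
      nImages = as.integer(K), nRounds = as.integer(R))
}

#' @describeIn trackVideo predicted per-frame IoU of a track
#' @param x a \code{TrafficLightTrack}
#' @export
setMethod("predictedIoU", "TrafficLightTrack", function(x) x@iou)

#' @describeIn trackVideo per-frame class labels of a track
#' @export
setMethod("frameClass", "TrafficLightTrack", function(x) x@tlClass)

setMethod("length", "TrafficLightTrack", function(x) length(x@iou))

setMethod("show", "TrafficLightTrack", function(object) {
  n <- length(object@iou)
  frac <- if (n) table(factor(object@tlClass,
                              c("green", "yellow", "red"))) / n else c(0, 0, 0)
  cat(sprintf(
    "TrafficLightTrack: %d frames (video=%s source=%s)\n  green %.1f%% | yellow %.1f%% | red %.1f%%  [green > %.2f, red < %.2f]\n",
    n, object@videoId, object@sourceId,
    100 * frac[1], 100 * frac[2], 100 * frac[3],
    object@greenMin, object@redMax))
})

#' @describeIn buildModel full layer sequence description
#' @export
setMethod("modelLayers", "IoURegressor", function(x) x@layers)

#' @describeIn buildModel head layer sequence (GAP, dense 256, dropout,
#'   dense 1)
#' @export
setMethod("headLayers", "IoURegressor", function(x) {
  x@layers[(length(x@layers) - 3L):length(x@layers)]
})

#' @describeIn trainRegressor per-epoch loss history of a trained model
#' @export
setMethod("trainHistory", "IoURegressor", function(x) x@history)

#' @describeIn buildModel total trainable parameter count
#' @export
setMethod("nParameters", "IoURegressor", function(x) {
  sum(vapply(unlist(x@params, recursive = FALSE, use.names = FALSE),
             length, 0L))
})

setMethod("show", "IoURegressor", function(object) {
  cat(sprintf("IoURegressor backbone='%s' input=%dx%dx3 params=%d %s\n",
              object@backbone, object@inputSide, object@inputSide,
              nParameters(object),
              if (object@trained) sprintf("(trained, loss=%s)", object@loss)
              else "(untrained)"))
  cat("  layers:", paste(object@layers, collapse = " -> "), "\n")
})
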