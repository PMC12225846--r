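#' @include AllClasses.R
NULL

.TL_COLORS <- list(green = c(0.20, 0.70, 0.29),
                   yellow = c(1.00, 0.76, 0.03),
                   red = c(0.84, 0.19, 0.15))

#' Traffic-light classification of IoU scores
#'
#' Green for high predicted quality (IoU above \code{greenMin}), red for
#' low (below \code{redMax}), yellow in between; the boundary values
#' themselves are yellow. A total, deterministic, monotone step function.
#'
#' @param iou numeric vector of (predicted) IoU values.
#' @param greenMin lower open bound of the green class.
#' @param redMax upper open bound of the red class; must be <=
#'   \code{greenMin}.
#' @return character vector in \{"green", "yellow", "red"\}.
#' @examples
#' classifyIoU(c(0.75, 0.65, 0.55))
#' @export
classifyIoU <- function(iou, greenMin = 0.7, redMax = 0.6) {
  if (redMax > greenMin) {
    stop(sprintf("inverted thresholds: redMax (%g) > greenMin (%g)",
                 redMax, greenMin))
  }
  out <- rep("yellow", length(iou))
  out[iou > greenMin] <- "green"
  out[iou < redMax] <- "red"
  out
}

#' Per-frame quality tracks for a video
#'
#' Runs the quality model over every frame and candidate mask of each
#' segmentation source, producing one [TrafficLightTrack-class] per
#' source: frame-wise predicted IoU plus its traffic-light class.
#'
#' @param frames list of grayscale frame matrices (or
#'   [FramePair-class] objects, whose images are used; their masks are
#'   ignored).
#' @param candidateMasks either a list of binary masks (one source) or a
#'   named list of such lists (one per segmentation source), each the same
#'   length as \code{frames}.
#' @param model a trained [IoURegressor-class].
#' @param scheme channel scheme code.
#' @param greenMin,redMax traffic-light thresholds.
#' @param videoId,modelId labels stored on the tracks.
#' @return named list of [TrafficLightTrack-class] objects.
#' @export
trackVideo <- function(frames, candidateMasks, model, scheme = "see",
                       greenMin = 0.7, redMax = 0.6,
                       videoId = NA_character_, modelId = NA_character_) {
  multi <- length(candidateMasks) > 0L && is.list(candidateMasks[[1L]]) &&
    !is.matrix(candidateMasks[[1L]])
  sources <- if (multi) candidateMasks else list(source1 = candidateMasks)
  if (is.null(names(sources))) {
    names(sources) <- sprintf("source%d", seq_along(sources))
  }
  out <- lapply(names(sources), function(srcName) {
    masks <- sources[[srcName]]
    if (length(masks) != length(frames)) {
      stop(sprintf("source '%s' has %d masks for %d frames", srcName,
                   length(masks), length(frames)))
    }
    preds <- vapply(seq_along(frames), function(t) {
      predictIoU(model, frames[[t]], masks[[t]], scheme)
    }, 0)
    new("TrafficLightTrack", iou = as.numeric(preds),
        tlClass = classifyIoU(as.numeric(preds), greenMin, redMax),
        greenMin = greenMin, redMax = redMax,
        videoId = as.character(videoId), sourceId = srcName,
        modelId = as.character(modelId))
  })
  names(out) <- names(sources)
  out
}

#' Render a traffic-light bar
#'
#' Produces a horizontal RGB bar one pixel-column per frame (optionally
#' down-scaled for long videos) plus the per-frame CSV table
#' (frame, iou, class) and the class fractions.
#'
#' @param track a [TrafficLightTrack-class].
#' @param pngPath optional path for the bar PNG.
#' @param csvPath optional path for the CSV.
#' @param height bar height in pixels.
#' @param maxWidth optional maximum bar width; longer tracks are
#'   down-sampled by taking every ceiling(n/maxWidth)-th frame.
#' @return (invisibly) list with \code{image} (height x width x 3 array),
#'   \code{table} (data.frame frame/iou/class) and \code{fractions}.
#' @export
renderBar <- function(track, pngPath = NULL, csvPath = NULL, height = 12L,
                      maxWidth = NULL) {
  n <- length(track)
  cls <- frameClass(track)
  shown <- seq_len(n)
  if (!is.null(maxWidth) && n > maxWidth) {
    shown <- seq(1L, n, by = ceiling(n / maxWidth))
  }
  img <- array(0, c(height, length(shown), 3L))
  for (ci in 1:3) {
    img[, , ci] <- matrix(vapply(cls[shown],
                                 function(cl) .TL_COLORS[[cl]][ci], 0),
                          height, length(shown), byrow = TRUE)
  }
  tab <- data.frame(frame = seq_len(n), iou = predictedIoU(track),
                    class = cls, stringsAsFactors = FALSE)
  frac <- if (n) {
    as.numeric(table(factor(cls, c("green", "yellow", "red")))) / n
  } else c(0, 0, 0)
  names(frac) <- c("green", "yellow", "red")
  if (!is.null(pngPath) && length(shown)) png::writePNG(img, pngPath)
  if (!is.null(csvPath)) {
    utils::write.csv(tab, csvPath, row.names = FALSE, quote = FALSE)
  }
  invisible(list(image = img, table = tab, fractions = frac))
}
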