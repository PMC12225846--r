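#' Intersection over Union of two binary masks
#'
#' Computes \eqn{|A \cap B| / |A \cup B|} for two binary masks of equal
#' dimensions. When both masks are entirely empty the score is defined as
#' \code{emptyValue} (default 1): both raters agree there is no object,
#' which is the relevant reading for closed-glottis frames and avoids NaNs
#' propagating into reliability averages.
#'
#' @param a,b binary matrices (0/1) of identical dimensions.
#' @param emptyValue score returned when both masks are empty.
#' @return numeric in \[0, 1\].
#' @examples
#' a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
#' b <- matrix(0, 4, 4); b[1:2, 2:3] <- 1
#' iou(a, b)  # 2 / 6
#' @export
iou <- function(a, b, emptyValue = 1) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("mask dimensions differ: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
  }
  af <- a > 0.5
  bf <- b > 0.5
  uni <- sum(af | bf)
  if (uni == 0L) return(emptyValue)
  sum(af & bf) / uni
}

#' Convert between IoU and Dice scores
#'
#' The two overlap scores are deterministic monotone transforms of each
#' other: \eqn{D = 2J/(1+J)} and \eqn{J = D/(2-D)}.
#'
#' @param i,d numeric vector in \[0, 1\].
#' @return numeric vector in \[0, 1\].
#' @examples
#' diceFromIoU(1/3)   # 0.5
#' iouFromDice(0.5)   # 1/3
#' @export
diceFromIoU <- function(i) {
  if (any(i < 0 | i > 1)) stop("IoU values must lie in [0, 1]")
  2 * i / (1 + i)
}

#' @rdname diceFromIoU
#' @export
iouFromDice <- function(d) {
  if (any(d < 0 | d > 1)) stop("Dice values must lie in [0, 1]")
  d / (2 - d)
}

#' Equal-width binning of the IoU range
#'
#' \code{binSpec} describes a partition of \[0, 1\] into \code{nBins} bins of
#' equal width (the balanced-dataset default is 20 bins of width 0.05).
#' \code{binIndex} maps IoU values to 0-based bin indices: bins are
#' half-open \[k*w, (k+1)*w) except the last, which is closed so that 1.0
#' falls in bin \code{nBins - 1}.
#'
#' @param nBins positive integer number of bins.
#' @param width bin width; defaults to \code{1 / nBins} and must satisfy
#'   \code{nBins * width == 1} up to floating tolerance.
#' @return \code{binSpec}: a list with \code{nBins} and \code{width};
#'   \code{binIndex}: integer vector of bin indices in
#'   \code{0:(nBins - 1)}.
#' @examples
#' spec <- binSpec(20)
#' binIndex(c(0, 0.372, 1), spec)  # 0 7 19
#' @export
binSpec <- function(nBins = 20L, width = NULL) {
  nBins <- as.integer(nBins)
  if (nBins < 1L) stop("nBins must be >= 1")
  if (is.null(width)) width <- 1 / nBins
  if (abs(nBins * width - 1) > 1e-9) {
    stop(sprintf("nBins * width must equal 1 (got %d * %g = %g)",
                 nBins, width, nBins * width))
  }
  structure(list(nBins = nBins, width = width), class = "binSpec")
}

#' @rdname binSpec
#' @param x numeric vector of IoU values in \[0, 1\].
#' @param spec a \code{binSpec}.
#' @export
binIndex <- function(x, spec = binSpec()) {
  if (any(x < 0 | x > 1)) stop("IoU values must lie in [0, 1]")
  pmin(as.integer(floor(x / spec$width)), spec$nBins - 1L)
}

#' Root-mean-square error
#'
#' @param predicted,truth numeric vectors of equal, nonzero length.
#' @return numeric scalar.
#' @examples
#' rmse(c(1, 0), c(0, 0))  # sqrt(0.5)
#' @export
rmse <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("inputs must be non-empty")
  if (length(predicted) != length(truth)) {
    stop(sprintf("length mismatch: %d vs %d",
                 length(predicted), length(truth)))
  }
  sqrt(mean((predicted - truth)^2))
}

#' Read and write binary masks as single-channel PNG
#'
#' Masks are stored with background 0 and foreground 255; on read, values
#' above 127 (on the 0-255 scale) are foreground. Multi-channel PNGs are
#' collapsed to grayscale first.
#'
#' @param path file path.
#' @return \code{readMaskPNG}: a 0/1 matrix. \code{writeMaskPNG}: the path,
#'   invisibly.
#' @export
readMaskPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- rgbToGray(x)
  .binarize(x, threshold = 127 / 255)
}

#' @rdname readMaskPNG
#' @param mask binary matrix.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(.binarize(mask), path)
  invisible(path)
}

#' Read a grayscale image PNG onto the \[0, 255\] scale
#'
#' @param path file path.
#' @return numeric matrix with values in \[0, 255\].
#' @export
readImagePNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- rgbToGray(x)
  x * 255
}

#' @rdname readImagePNG
#' @param image numeric matrix in \[0, 255\].
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}
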