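#' @include AllClasses.R
NULL

#' Mean per-pixel mask of one rater over all rounds
#'
#' \eqn{\bar X_{i,k} = \frac{1}{R}\sum_r X_{i,k,r}}: a continuous grid in
#' \[0, 1\] whose support (values > 0) equals the union of the rater's
#' rounds for that image.
#'
#' @param set a [RaterAnnotationSet-class].
#' @param i rater index.
#' @param k image index.
#' @return numeric matrix in \[0, 1\].
#' @export
meanRoundMask <- function(set, i, k) {
  rounds <- set@masks[[i]][[k]]
  Reduce(`+`, rounds) / length(rounds)
}

#' Inter-rater reliability between one pair of raters
#'
#' Eq-style IeRR: each rater's masks are averaged over rounds, thresholded
#' at > 0 (equivalently: the union over rounds), and the IoU of the two
#' thresholded masks is averaged over all images:
#' \deqn{IeRR(i,j) = \frac{1}{K}\sum_k IoU(1(\bar X_{i,k} > 0),
#'   1(\bar X_{j,k} > 0)).}
#'
#' @param set a [RaterAnnotationSet-class].
#' @param i,j distinct rater indices.
#' @param images optional subset of image indices to average over.
#' @return numeric in \[0, 1\].
#' @export
ierrPair <- function(set, i, j, images = seq_len(nImages(set))) {
  if (i == j) stop("ierrPair requires two distinct raters (got i == j)")
  vals <- vapply(images, function(k) {
    ui <- .binarize(meanRoundMask(set, i, k), threshold = 0)
    uj <- .binarize(meanRoundMask(set, j, k), threshold = 0)
    iou(ui, uj)
  }, 0)
  mean(vals)
}

#' All pairwise inter-rater reliabilities
#'
#' @param set a [RaterAnnotationSet-class].
#' @param images optional subset of image indices.
#' @return symmetric \code{N x N} matrix with \code{NA} on the diagonal.
#' @export
ierrMatrix <- function(set, images = seq_len(nImages(set))) {
  N <- nRaters(set)
  m <- matrix(NA_real_, N, N)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      m[i, j] <- m[j, i] <- ierrPair(set, i, j, images)
    }
  }
  m
}

#' Intra-rater reliability of one rater
#'
#' Mean IoU over all pairwise round combinations, averaged over images:
#' \deqn{IaRR(i) = \frac{1}{\binom{R}{2}}\sum_{r<s}\frac{1}{K}\sum_k
#'   IoU(X_{i,k,r}, X_{i,k,s}).}
#' Requires at least two rounds.
#'
#' @param set a [RaterAnnotationSet-class].
#' @param i rater index.
#' @param images optional subset of image indices.
#' @return numeric in \[0, 1\].
#' @export
iarr <- function(set, i, images = seq_len(nImages(set))) {
  R <- nRounds(set)
  if (R < 2L) stop("iarr requires at least 2 rounds")
  prs <- utils::combn(R, 2L)
  vals <- apply(prs, 2L, function(rs) {
    mean(vapply(images, function(k) {
      iou(set@masks[[i]][[k]][[rs[1]]], set@masks[[i]][[k]][[rs[2]]])
    }, 0))
  })
  mean(vals)
}

#' @rdname iarr
#' @return \code{iarrVector}: numeric vector over all raters.
#' @export
iarrVector <- function(set, images = seq_len(nImages(set))) {
  vapply(seq_len(nRaters(set)), function(i) iarr(set, i, images), 0)
}

# mean foreground area of image k across all raters and rounds
.consensusAreas <- function(set) {
  vapply(seq_len(nImages(set)), function(k) {
    mean(vapply(seq_len(nRaters(set)), function(i) {
      mean(vapply(seq_len(nRounds(set)), function(r) {
        sum(set@masks[[i]][[k]][[r]])
      }, 0))
    }, 0))
  }, 0)
}

#' Area-stratified reliability
#'
#' Groups images by their consensus area (mean foreground pixel count over
#' all raters and rounds) into strata -- by default (0, 20), \[20, 200\]
#' and (200, Inf) pixels, the regimes where manual annotations behave very
#' differently -- and recomputes mean IeRR and IaRR within each stratum.
#' Images with consensus area 0 and empty strata are omitted.
#'
#' @param set a [RaterAnnotationSet-class].
#' @param areaEdges increasing positive breakpoints; \code{c(a, b)} yields
#'   strata (0, a), \[a, b\], (b, Inf).
#' @return \code{data.frame} with one row per non-empty stratum: label,
#'   image count, mean IeRR, mean IaRR.
#' @export
stratifyByArea <- function(set, areaEdges = c(20L, 200L)) {
  stopifnot(length(areaEdges) == 2L, diff(areaEdges) > 0)
  areas <- .consensusAreas(set)
  strata <- list(
    list(label = sprintf("(0,%d)", areaEdges[1]),
         images = which(areas > 0 & areas < areaEdges[1])),
    list(label = sprintf("[%d,%d]", areaEdges[1], areaEdges[2]),
         images = which(areas >= areaEdges[1] & areas <= areaEdges[2])),
    list(label = sprintf("(%d,Inf)", areaEdges[2]),
         images = which(areas > areaEdges[2])))
  rows <- lapply(strata, function(st) {
    if (!length(st$images)) return(NULL)
    ie <- if (nRaters(set) > 1L) {
      mean(ierrMatrix(set, st$images), na.rm = TRUE)
    } else NA_real_
    ia <- if (nRounds(set) > 1L) {
      mean(iarrVector(set, st$images))
    } else NA_real_
    data.frame(stratum = st$label, nImages = length(st$images),
               meanIeRR = ie, meanIaRR = ia, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(stratum = character(), nImages = integer(),
                      meanIeRR = numeric(), meanIaRR = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Rater agreement as a function of distance from the glottis
#'
#' For every image, a majority-vote consensus mask is formed over all
#' raters and rounds; the per-pixel agreement is the fraction of masks that
#' match the consensus at that pixel. Agreement is then averaged in rings
#' of (a) normalized distance from the consensus centre of mass and (b)
#' signed distance from the consensus boundary (negative inside), each
#' normalized per image by the consensus' maximum centre-of-mass distance,
#' making the profiles scale-free across glottis sizes. Images with an
#' empty consensus are skipped.
#'
#' @param set a [RaterAnnotationSet-class].
#' @param i optional rater index: profile of that rater's rounds against
#'   their own consensus (intra-rater flavour); default uses all raters.
#' @param nRings number of distance rings.
#' @return \code{data.frame} with columns \code{metric} ("com" or "edge"),
#'   \code{ring}, \code{mid} (ring-centre normalized distance) and
#'   \code{agreement} in \[0, 1\].
#' @export
agreementVsDistance <- function(set, i = NULL, nRings = 10L) {
  raters <- if (is.null(i)) seq_len(nRaters(set)) else i
  comBreaks <- seq(0, 1, length.out = nRings + 1L)
  edgeBreaks <- seq(-1, 1, length.out = nRings + 1L)
  comAcc <- comN <- numeric(nRings)
  edgeAcc <- edgeN <- numeric(nRings)
  for (k in seq_len(nImages(set))) {
    stack <- unlist(lapply(raters, function(ri) set@masks[[ri]][[k]]),
                    recursive = FALSE)
    p <- Reduce(`+`, stack) / length(stack)
    consensus <- .binarize(p)             # majority vote (> 0.5)
    if (!any(consensus > 0)) next
    agree <- ifelse(consensus > 0, p, 1 - p)
    ij <- which(consensus > 0, arr.ind = TRUE)
    cy <- mean(ij[, 1]); cx <- mean(ij[, 2])
    r <- matrix(seq_len(nrow(p)), nrow(p), ncol(p))
    cc <- matrix(seq_len(ncol(p)), nrow(p), ncol(p), byrow = TRUE)
    dcom <- sqrt((r - cy)^2 + (cc - cx)^2)
    scale <- max(dcom[consensus > 0], 1)
    ndcom <- dcom / scale
    # signed distance from the consensus boundary: negative inside
    dOut <- .distToForeground(consensus)
    dIn <- .distToForeground(1 - consensus)
    nedge <- (dOut - dIn) / scale
    bcom <- findInterval(ndcom, comBreaks, rightmost.closed = TRUE)
    bedge <- findInterval(pmin(pmax(nedge, -1), 1), edgeBreaks,
                          rightmost.closed = TRUE)
    for (b in seq_len(nRings)) {
      selc <- bcom == b
      if (any(selc)) {
        comAcc[b] <- comAcc[b] + sum(agree[selc])
        comN[b] <- comN[b] + sum(selc)
      }
      sele <- bedge == b
      if (any(sele)) {
        edgeAcc[b] <- edgeAcc[b] + sum(agree[sele])
        edgeN[b] <- edgeN[b] + sum(sele)
      }
    }
  }
  mids <- function(br) (br[-1] + br[-length(br)]) / 2
  rbind(
    data.frame(metric = "com", ring = seq_len(nRings),
               mid = mids(comBreaks),
               agreement = ifelse(comN > 0, comAcc / comN, NA_real_)),
    data.frame(metric = "edge", ring = seq_len(nRings),
               mid = mids(edgeBreaks),
               agreement = ifelse(edgeN > 0, edgeAcc / edgeN, NA_real_)))
}

#' Full reliability report
#'
#' Convenience wrapper returning the IeRR matrix, the IaRR vector, their
#' means, and the default area strata in one list.
#'
#' @param set a [RaterAnnotationSet-class].
#' @return list with elements \code{ierrMatrix}, \code{iarrVector},
#'   \code{meanIeRR}, \code{meanIaRR}, \code{strata}.
#' @export
reliabilityReport <- function(set) {
  im <- if (nRaters(set) > 1L) ierrMatrix(set) else
    matrix(NA_real_, 1, 1)
  iv <- if (nRounds(set) > 1L) iarrVector(set) else NA_real_
  list(ierrMatrix = im, iarrVector = iv,
       meanIeRR = mean(im, na.rm = TRUE), meanIaRR = mean(iv),
       strata = stratifyByArea(set))
}
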