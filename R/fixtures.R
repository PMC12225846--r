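#' @include AllClasses.R artifact-generator.R
NULL

#' Construct a glottis phantom specification
#'
#' @param side frame side in pixels (square frames).
#' @param length,maxWidth spindle length and maximum width in pixels; the
#'   defaults give a mask area of roughly 2/3 * length * maxWidth ~ 370 px
#'   on a 64 px frame, comparable to a wide-open glottis.
#' @param orientation main-axis angle (radians).
#' @param centroidJitter maximum uniform centre jitter (pixels).
#' @param contrast intensity drop of the glottal gap below the background.
#' @param textureAmplitude amplitude of the smoothed background texture.
#' @param sizeJitter per-draw relative shrink range of length/width; the
#'   default makes mask areas span roughly 70-400 px on a 64 px frame,
#'   so glottis size is not a constant a model could memorize.
#' @param orientationJitter max per-draw axis rotation (radians).
#' @return A [GlottisPhantomSpec-class].
#' @export
glottisPhantomSpec <- function(side = 64L, length = 0.62 * side,
                               maxWidth = 0.22 * side,
                               orientation = pi / 2,
                               centroidJitter = side / 16,
                               contrast = 70, textureAmplitude = 25,
                               sizeJitter = 0.6,
                               orientationJitter = 0.35) {
  new("GlottisPhantomSpec", side = as.integer(side), length = length,
      maxWidth = maxWidth, orientation = orientation,
      centroidJitter = centroidJitter, contrast = contrast,
      textureAmplitude = textureAmplitude, sizeJitter = sizeJitter,
      orientationJitter = orientationJitter)
}

# border fuzz restricted to a random subset of the edge band: the round
# noise of a simulated rater, gentler than full-band fuzz
.partialBorderFuzz <- function(m, flipP, fraction) {
  band <- .edgeBand(m)
  idx <- which(band > 0)
  if (!length(idx)) return(.asMask(m))
  sel <- idx[stats::runif(length(idx)) < fraction]
  out <- .asMask(m)
  out[sel] <- as.double(stats::runif(length(sel)) < flipP)
  out
}

# per-draw subject geometry: shrink factors and axis rotation
.sampleGeometry <- function(spec) {
  list(lengthScale = stats::runif(1, 1 - spec@sizeJitter, 1),
       widthScale = stats::runif(1, 1 - spec@sizeJitter, 1),
       rot = stats::runif(1, -spec@orientationJitter,
                          spec@orientationJitter))
}

# spindle (lens with pointed ends) support mask; width w at the centre,
# tapering quadratically to 0 at +/- L/2 along the main axis
.spindleMask <- function(side, cy, cx, L, w, theta) {
  if (w <= 0 || L <= 0) return(matrix(0, side, side))
  r <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  u <- (r - cy) * cos(theta) + (cc - cx) * sin(theta)
  v <- -(r - cy) * sin(theta) + (cc - cx) * cos(theta)
  half <- (w / 2) * pmax(0, 1 - (2 * u / L)^2)
  matrix(as.double(abs(u) <= L / 2 & abs(v) < half), side, side)
}

.phantomFrame <- function(spec, widthScale = 1, geometry = NULL) {
  side <- spec@side
  if (is.null(geometry)) geometry <- .sampleGeometry(spec)
  cy <- side / 2 + stats::runif(1, -spec@centroidJitter, spec@centroidJitter)
  cx <- side / 2 + stats::runif(1, -spec@centroidJitter, spec@centroidJitter)
  mask <- .spindleMask(side, cy, cx, spec@length * geometry$lengthScale,
                       spec@maxWidth * geometry$widthScale * widthScale,
                       spec@orientation + geometry$rot)
  # textured background: smoothed white noise around a mid-gray plateau
  noise <- matrix(stats::rnorm(side * side), side, side)
  tex <- as.matrix(EBImage::gblur(noise, sigma = 2))
  img <- 150 + spec@textureAmplitude * tex / max(1e-8, stats::sd(tex))
  if (any(mask > 0)) {
    # bright vocal-fold rim just outside the gap, dark gap inside
    rim <- .distToForeground(mask)
    img[rim > 0 & rim <= 2] <- img[rim > 0 & rim <= 2] + 40
    img[mask > 0] <- img[mask > 0] - spec@contrast
  }
  framePair(pmin(pmax(img, 0), 255), mask)
}

#' Generate a synthetic glottis frame with its ground-truth mask
#'
#' Renders a spindle-shaped dark glottal gap with a bright rim on a
#' textured background; the mask is the exact spindle support.
#' Deterministic per \code{(spec, seed)}.
#'
#' @param spec a [GlottisPhantomSpec-class].
#' @param seed integer seed.
#' @param widthScale multiplier on \code{maxWidth} (0 gives a closed
#'   glottis with an empty mask).
#' @return A [FramePair-class].
#' @examples
#' fp <- makeGlottisPair(glottisPhantomSpec(side = 64), seed = 3)
#' sum(frameMask(fp))
#' @export
makeGlottisPair <- function(spec = glottisPhantomSpec(), seed,
                            widthScale = 1) {
  fp <- .withSeed(as.integer(seed), .phantomFrame(spec, widthScale))
  fp@sourceId <- sprintf("phantom_s%d", as.integer(seed))
  fp
}

#' Generate a synthetic oscillating glottis video
#'
#' Spindle width is modulated as \eqn{(1 - \cos(2\pi c t / n)) / 2} so the
#' glottal area sweeps from full closure (empty mask) to its maximum
#' \code{cycles} times, passing through small (< 20 px) and large
#' (> 200 px) areas on the way -- the regimes where rater reliability
#' differs most.
#'
#' @param spec a [GlottisPhantomSpec-class]; the default uses a mild
#'   subject-size jitter so peak areas exceed 200 px.
#' @param nFrames number of frames.
#' @param cycles number of open-close cycles.
#' @param seed integer seed.
#' @return list of [FramePair-class] objects of length \code{nFrames}.
#' @export
makeGlottisVideo <- function(spec = glottisPhantomSpec(sizeJitter = 0.15),
                             nFrames, cycles, seed) {
  nFrames <- as.integer(nFrames)
  phase <- (seq_len(nFrames) - 1) / nFrames
  scale <- (1 - cos(2 * pi * cycles * phase)) / 2
  .withSeed(as.integer(seed), {
    geometry <- .sampleGeometry(spec)   # one subject per video
    lapply(seq_len(nFrames), function(t) {
      fp <- .phantomFrame(spec, widthScale = scale[t], geometry = geometry)
      fp@sourceId <- sprintf("video_s%d_f%04d", as.integer(seed), t)
      fp
    })
  })
}

#' Construct a simulated-rater specification
#'
#' @param nRaters,nRounds grid dimensions.
#' @param raterBias signed per-rater morphology iterations (positive =
#'   dilate, negative = erode); default spreads raters evenly over
#'   \[-2, 2\].
#' @param noiseFlipP foreground probability for re-randomized band pixels.
#' @param noiseFraction fraction of the mask's edge band re-randomized in
#'   each round (the intra-rater noise level; 0 disables round noise).
#'   The default, together with the default bias spread, reproduces the
#'   human annotation regime where raters agree better with themselves
#'   across rounds than with each other.
#' @return A [SimulatedRaterSpec-class].
#' @export
simulatedRaterSpec <- function(nRaters = 6L, nRounds = 3L,
                               raterBias = round(seq(-2, 2,
                                                     length.out = nRaters)),
                               noiseFlipP = 0.5, noiseFraction = 0.3) {
  new("SimulatedRaterSpec", nRaters = as.integer(nRaters),
      nRounds = as.integer(nRounds), raterBias = as.numeric(raterBias),
      noiseFlipP = noiseFlipP, noiseFraction = noiseFraction)
}

#' Simulate a multi-rater, multi-round annotation study
#'
#' Each rater's annotation of image k in round r is the ground-truth mask
#' deformed by that rater's systematic bias (iterated dilation or erosion,
#' identical across rounds) plus independent per-round border fuzz. With
#' bias exceeding round noise, between-rater disagreement exceeds
#' within-rater disagreement, so mean IaRR > mean IeRR by construction.
#'
#' @param pairs list of [FramePair-class] ground-truth frames (the K
#'   images).
#' @param spec a [SimulatedRaterSpec-class].
#' @param seed integer seed.
#' @return A [RaterAnnotationSet-class].
#' @examples
#' pairs <- lapply(1:3, function(s) makeGlottisPair(seed = s))
#' rs <- makeRaterSet(pairs, simulatedRaterSpec(nRaters = 2, nRounds = 2),
#'                    seed = 1)
#' nRaters(rs)
#' @export
makeRaterSet <- function(pairs, spec = simulatedRaterSpec(), seed) {
  .withSeed(as.integer(seed), {
    masks <- lapply(seq_len(spec@nRaters), function(i) {
      bias <- round(spec@raterBias[i])
      lapply(pairs, function(fp) {
        gt <- frameMask(fp)
        biased <- if (bias == 0 || !any(gt > 0)) gt else {
          applyUniformScaling(gt, abs(bias),
                              if (bias > 0) "dilate" else "erode")
        }
        lapply(seq_len(spec@nRounds), function(r) {
          if (spec@noiseFraction > 0) {
            .partialBorderFuzz(biased, spec@noiseFlipP,
                               spec@noiseFraction)
          } else biased
        })
      })
    })
    raterAnnotationSet(masks)
  })
}
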