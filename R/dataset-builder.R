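#' @include AllClasses.R artifact-generator.R iou-metrics.R
NULL

.SCHEMES <- c("eee", "sss", "see", "sse", "ees", "ess")

#' Crop a frame square around the glottis and resize
#'
#' Takes the largest square window centred on the mask's bounding-box
#' centre (clipped to the image bounds; image centre when the mask is
#' empty) and resizes it to \code{side x side}: bilinear for the image,
#' nearest-neighbour for the mask, which is re-binarized.
#'
#' @param p a [FramePair-class].
#' @param side output side in pixels.
#' @return A [FramePair-class] of dimensions \code{side x side}.
#' @export
cropAndResize <- function(p, side = 224L) {
  img <- frameImage(p); msk <- frameMask(p)
  if (nrow(img) < 8L || ncol(img) < 8L) {
    stop(sprintf("image too small to crop: %dx%d (need at least 8x8)",
                 nrow(img), ncol(img)))
  }
  w <- .cropWindow(msk)
  out <- .cropResizeOne(img, w, side, binary = FALSE)
  outm <- .cropResizeOne(msk, w, side, binary = TRUE)
  framePair(pmin(pmax(out, 0), 255), outm, sourceId = sourceId(p))
}

# largest inscribed square window centred on the mask bbox centre
.cropWindow <- function(msk) {
  nr <- nrow(msk); nc <- ncol(msk)
  s <- min(nr, nc)
  if (any(msk > 0)) {
    ij <- which(msk > 0, arr.ind = TRUE)
    cy <- mean(range(ij[, 1])); cx <- mean(range(ij[, 2]))
  } else {
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  }
  r0 <- min(max(1L, round(cy - s / 2)), nr - s + 1L)
  c0 <- min(max(1L, round(cx - s / 2)), nc - s + 1L)
  list(r = r0:(r0 + s - 1L), c = c0:(c0 + s - 1L))
}

.cropResizeOne <- function(x, w, side, binary) {
  cropped <- x[w$r, w$c, drop = FALSE]
  if (nrow(cropped) == side && ncol(cropped) == side) {
    return(if (binary) .binarize(cropped) else cropped)
  }
  filt <- if (binary) "none" else "bilinear"
  out <- as.matrix(EBImage::resize(cropped, w = side, h = side,
                                   filter = filt))
  if (binary) .binarize(out) else out
}

#' Normalize intensities from \[0, 255\] to \[-1, 1\]
#'
#' @param x numeric matrix or array on the \[0, 255\] scale.
#' @return same shape, mapped by \code{x / 127.5 - 1}.
#' @export
normalizeImage <- function(x) x / 127.5 - 1

#' Compose a 3-channel network input from image and mask channels
#'
#' Assembles the \code{H x W x 3} input tensor for the IoU regressor
#' according to a scheme code over \{e, s\}: channel c holds the normalized
#' endoscopy image where \code{scheme[c] == "e"} and the candidate
#' (degraded or predicted) mask, mapped to \{-1, 1\}, where
#' \code{scheme[c] == "s"}. RGB images must be converted to grayscale
#' beforehand (framePair does this on construction).
#'
#' @param p a [FramePair-class] (already preprocessed to the network side).
#' @param degraded binary candidate mask with the frame's dimensions.
#' @param scheme one of \code{"eee", "sss", "see", "sse", "ees", "ess"}.
#' @return \code{H x W x 3} array in \[-1, 1\] with attribute
#'   \code{"scheme"}.
#' @export
composeInput <- function(p, degraded, scheme) {
  if (!is.character(scheme) || length(scheme) != 1L ||
      !scheme %in% .SCHEMES) {
    stop(sprintf("invalid scheme '%s'; valid codes are: %s",
                 paste(scheme, collapse = ","),
                 paste(.SCHEMES, collapse = ", ")))
  }
  img <- frameImage(p)
  if (!identical(dim(img), dim(degraded))) {
    stop("frame and candidate mask dimensions differ")
  }
  e <- normalizeImage(img)
  s <- .binarize(degraded) * 2 - 1
  chans <- strsplit(scheme, "")[[1]]
  out <- array(0, c(nrow(img), ncol(img), 3L))
  for (ci in 1:3) out[, , ci] <- if (chans[ci] == "e") e else s
  attr(out, "scheme") <- scheme
  out
}

#' Corruption config targeted at one IoU bin
#'
#' The balanced-dataset sampler fills low- and high-IoU bins by annealing
#' the corruption strength towards the bin it is trying to fill: near-1
#' bins get only a few small discs, mid bins get border fuzz, morphology
#' and mid-quantile Perlin blobs, and near-0 bins get erosion past
#' vanishing plus Perlin floods. Adjacent bins with similar severity share
#' one recipe (a "band", see [annealBand()]); the mapping depends only on
#' \code{(cfg, bin, spec)}, so a manifest row's draw is replayable from
#' its recorded bin and seed. Recipes were calibrated on the 64 px glottis
#' phantom so that every bin receives a usable share of its band's draws.
#'
#' @param cfg the base [CorruptionConfig-class] (proximity, Perlin mode,
#'   periods and edge-flip probability are inherited).
#' @param bin 0-based target bin.
#' @param spec a [binSpec()].
#' @return A [CorruptionConfig-class].
#' @export
annealConfig <- function(cfg, bin, spec = binSpec()) {
  ap <- function(sc, bf, sm, lg) c(scaling = sc, borderFuzz = bf,
                                   smallArtifacts = sm, largeArtifacts = lg)
  recipes <- list(
    list(p = ap(1, 0, 0, 0.4), it = c(7L, 9L), ms = 3L, rr = c(1L, 2L),
         qr = c(0.90, 0.97)),                 # ~0: erode away (+small blob)
    list(p = ap(1, 0, 0, 1), it = c(6L, 8L), ms = 3L, rr = c(1L, 2L),
         qr = c(0.70, 0.90)),                 # sliver + blob
    list(p = ap(1, 0.4, 0, 0.8), it = c(4L, 5L), ms = 3L, rr = c(1L, 2L),
         qr = c(0.60, 0.80)),                 # heavy erosion + wide blob
    list(p = ap(0.3, 0.3, 0, 1), it = c(2L, 3L), ms = 3L, rr = c(1L, 2L),
         qr = c(0.78, 0.88)),
    list(p = ap(0, 0, 0, 1), it = c(1L, 1L), ms = 3L, rr = c(1L, 2L),
         qr = c(0.885, 0.925)),               # mid: Perlin blobs alone
    list(p = ap(0, 0, 0, 1), it = c(1L, 1L), ms = 3L, rr = c(1L, 2L),
         qr = c(0.925, 0.965)),
    list(p = ap(0.3, 1, 0.4, 0), it = c(1L, 1L), ms = 3L, rr = c(1L, 2L),
         qr = c(0.99, 1.0)),                  # border fuzz core
    list(p = ap(1, 0, 1, 0), it = c(1L, 1L), ms = 4L, rr = c(2L, 3L),
         qr = c(0.99, 1.0)),
    list(p = ap(1, 0, 0.4, 0), it = c(1L, 1L), ms = 3L, rr = c(1L, 2L),
         qr = c(0.99, 1.0)),                  # one morphology pass
    list(p = ap(0, 0, 1, 0), it = c(1L, 1L), ms = 4L, rr = c(1L, 2L),
         qr = c(0.99, 1.0)),                  # a few discs
    list(p = ap(0, 0, 1, 0), it = c(1L, 1L), ms = 2L, rr = c(1L, 1L),
         qr = c(0.99, 1.0)))                  # ~1: 1-2 tiny discs
  o <- recipes[[annealBand(bin, spec) + 1L]]
  corruptionConfig(pApply = o$p,
                   scalingIterationsRange = o$it,
                   edgeFlipProbability = cfg@edgeFlipProbability,
                   maxSpheres = o$ms, sphereRadiusRange = o$rr,
                   sphereProximity = cfg@sphereProximity,
                   perlinPeriodsRange = cfg@perlinPeriodsRange,
                   perlinThresholdRange = o$qr,
                   perlinMode = cfg@perlinMode)
}

#' @rdname annealConfig
#' @details \code{annealBand} maps a bin to its severity band (0-10).
#'   Bins in one band share an identical annealed config, so during
#'   balanced sampling a draw targeted at one bin may be banked into any
#'   unfilled bin of the same band without breaking replayability. For the
#'   default 20-bin spec the bands are \{0\}, \{1\}, \{2,3\}, \{4,5\},
#'   \{6,7\}, \{8,9\}, \{10,11\}, \{12,13\}, \{14,15\}, \{16,17,18\},
#'   \{19\}.
#' @export
annealBand <- function(bin, spec = binSpec()) {
  cc <- (bin + 0.5) * spec$width
  findInterval(cc, c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70,
                     0.80, 0.95))
}

#' Build an IoU-balanced corruption dataset
#'
#' Rejection-samples corrupted masks until every IoU bin holds exactly
#' \code{perBin} samples (total \code{nBins * perBin}). With
#' \code{anneal = TRUE} (default) each attempt targets the currently
#' neediest bin with a bin-matched corruption strength (see
#' [annealConfig()]) and is accepted only into an unfilled bin of the same
#' severity band, which keeps every row replayable from
#' \code{(cfg, bin, seed)}; with \code{anneal = FALSE}
#' plain rejection sampling under \code{cfg} accepts into any unfilled bin.
#'
#' @param pairs list of [FramePair-class] ground-truth frames.
#' @param spec a [binSpec()] (20 bins of width 0.05 by default).
#' @param perBin samples per bin.
#' @param cfg base [CorruptionConfig-class].
#' @param seed master seed; the manifest is a deterministic function of
#'   \code{(pairs, spec, perBin, cfg, seed)}.
#' @param maxAttemptsPerBin attempts allowed per bin before failing;
#'   defaults to 30 draws per requested sample (every calibrated band
#'   recipe lands in each of its bins far more often than 1 in 30).
#' @param anneal use bin-targeted corruption annealing.
#' @param maskDir optional directory; when given, every degraded mask is
#'   written there as a PNG and referenced from \code{mask_path}.
#' @return manifest \code{data.frame} with columns \code{sample_id},
#'   \code{source_id}, \code{mask_path}, \code{true_iou}, \code{bin},
#'   \code{seed}.
#' @examples
#' pairs <- lapply(1:5, function(s) makeGlottisPair(seed = s))
#' man <- buildBalancedDataset(pairs, binSpec(20), perBin = 2, seed = 1)
#' table(man$bin)
#' @export
buildBalancedDataset <- function(pairs, spec = binSpec(), perBin,
                                 cfg = corruptionConfig(), seed,
                                 maxAttemptsPerBin = max(2000L,
                                                         30L * perBin),
                                 anneal = TRUE, maskDir = NULL) {
  if (!length(pairs)) stop("pairs must be non-empty")
  if (perBin < 1L) stop("perBin must be >= 1")
  nB <- spec$nBins
  srcIds <- vapply(pairs, sourceId, "")
  if (anyNA(srcIds) || anyDuplicated(srcIds)) {
    srcIds <- sprintf("pair_%03d", seq_along(pairs))
  }
  if (!is.null(maskDir) && !dir.exists(maskDir)) {
    dir.create(maskDir, recursive = TRUE)
  }
  binCfgs <- if (anneal) {
    lapply(0:(nB - 1L), function(b) annealConfig(cfg, b, spec))
  } else NULL

  .withSeed(as.integer(seed), {
    fill <- integer(nB)           # per-bin accepted counts
    tried <- integer(nB)          # per-bin attempt counts
    total <- nB * perBin
    rows <- vector("list", total)
    got <- 0L
    while (got < total) {
      need <- perBin - fill
      target <- which.max(need) - 1L      # neediest bin, lowest index wins
      if (tried[target + 1L] >= maxAttemptsPerBin) {
        stop(sprintf(
          "bin %d still holds %d/%d samples after %d attempts",
          target, fill[target + 1L], perBin, tried[target + 1L]))
      }
      tried[target + 1L] <- tried[target + 1L] + 1L
      pi <- sample.int(length(pairs), 1L)
      sd <- sample.int(2147483646L, 1L)
      acfg <- if (anneal) binCfgs[[target + 1L]] else cfg
      ds <- degradeMask(pairs[[pi]], acfg, sd, ensureApplied = TRUE)
      b <- binIndex(trueIoU(ds), spec)
      accept <- if (anneal) {
        annealBand(b, spec) == annealBand(target, spec) &&
          fill[b + 1L] < perBin
      } else fill[b + 1L] < perBin
      if (!accept) next
      fill[b + 1L] <- fill[b + 1L] + 1L
      got <- got + 1L
      maskPath <- NA_character_
      if (!is.null(maskDir)) {
        maskPath <- file.path(maskDir, sprintf("s%06d.png", got))
        writeMaskPNG(degradedMask(ds), maskPath)
      }
      rows[[got]] <- data.frame(
        sample_id = sprintf("s%06d", got), source_id = srcIds[pi],
        mask_path = maskPath, true_iou = trueIoU(ds), bin = b, seed = sd,
        stringsAsFactors = FALSE)
    }
    man <- do.call(rbind, rows)
    man <- man[order(man$bin, man$sample_id), , drop = FALSE]
    rownames(man) <- NULL
    attr(man, "binSpec") <- spec
    attr(man, "anneal") <- anneal
    man
  })
}

#' Replay one manifest row into its degraded sample
#'
#' @param pair the [FramePair-class] named by the row's \code{source_id}.
#' @param cfg the base config the manifest was built with.
#' @param bin,seed the row's recorded bin and seed.
#' @param spec the [binSpec()] used.
#' @param anneal whether the manifest was built with annealing.
#' @return A [DegradedSample-class] bit-identical to the original draw.
#' @export
replaySample <- function(pair, cfg, bin, seed, spec = binSpec(),
                         anneal = TRUE) {
  acfg <- if (anneal) annealConfig(cfg, bin, spec) else cfg
  degradeMask(pair, acfg, seed, ensureApplied = TRUE)
}

#' Stratified train/validation split of a manifest
#'
#' Splits \code{round(valFraction * nrow)} rows into the validation set,
#' stratified by bin: each bin contributes its floor share first and the
#' remaining validation slots go to the bins with the largest fractional
#' remainders (ties resolved by bin order), so a balanced manifest stays
#' balanced. Selection within a bin is uniformly random.
#'
#' @param manifest a manifest \code{data.frame} with a \code{bin} column.
#' @param valFraction fraction of rows for validation.
#' @param seed integer seed.
#' @return \code{list(train =, validation =)} of disjoint manifests whose
#'   union is the input.
#' @export
splitManifest <- function(manifest, valFraction = 0.05, seed) {
  n <- nrow(manifest)
  nVal <- round(valFraction * n)
  bins <- sort(unique(manifest$bin))
  perBin <- vapply(bins, function(b) sum(manifest$bin == b), 0L)
  exact <- valFraction * perBin
  base <- floor(exact)
  rem <- nVal - sum(base)
  quota <- base
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  } else if (rem < 0) {
    drop <- order(exact - base)[seq_len(-rem)]
    quota[drop] <- pmax(0L, quota[drop] - 1L)
  }
  .withSeed(as.integer(seed), {
    valIdx <- integer(0)
    for (bi in seq_along(bins)) {
      rows <- which(manifest$bin == bins[bi])
      if (quota[bi] > 0) {
        valIdx <- c(valIdx, rows[sample.int(length(rows), quota[bi])])
      }
    }
    valIdx <- sort(valIdx)
    list(train = manifest[setdiff(seq_len(n), valIdx), , drop = FALSE],
         validation = manifest[valIdx, , drop = FALSE])
  })
}

#' Materialize manifest rows into network tensors
#'
#' Replays every row's degradation, preprocesses frames to the network
#' side, and composes the scheme channels.
#'
#' @param pairs the ground-truth frame list the manifest was built from.
#' @param manifest a manifest \code{data.frame}.
#' @param cfg the base [CorruptionConfig-class] used to build it.
#' @param scheme channel scheme code.
#' @param side network input side; frames are crop/resized when they
#'   differ.
#' @param spec the [binSpec()] used.
#' @param anneal whether the manifest was built with annealing.
#' @return \code{list(x = H x W x 3 x N array, y = numeric(N))}.
#' @export
makeRegressionTensors <- function(pairs, manifest, cfg, scheme,
                                  side = NULL, spec = binSpec(),
                                  anneal = TRUE) {
  srcIds <- vapply(pairs, sourceId, "")
  if (anyNA(srcIds) || anyDuplicated(srcIds)) {
    srcIds <- sprintf("pair_%03d", seq_along(pairs))
  }
  n <- nrow(manifest)
  if (!n) stop("manifest is empty")
  lookup <- match(manifest$source_id, srcIds)
  if (anyNA(lookup)) stop("manifest source_id not found among pairs")
  p1 <- pairs[[lookup[1]]]
  outSide <- if (is.null(side)) nrow(frameImage(p1)) else as.integer(side)
  x <- array(0, c(outSide, outSide, 3L, n))
  y <- numeric(n)
  for (ri in seq_len(n)) {
    pair <- pairs[[lookup[ri]]]
    ds <- replaySample(pair, cfg, manifest$bin[ri], manifest$seed[ri],
                       spec, anneal)
    deg <- degradedMask(ds)
    if (nrow(frameImage(pair)) != outSide ||
        ncol(frameImage(pair)) != outSide) {
      w <- .cropWindow(frameMask(pair))
      pair <- framePair(
        pmin(pmax(.cropResizeOne(frameImage(pair), w, outSide, FALSE),
                  0), 255),
        .cropResizeOne(frameMask(pair), w, outSide, TRUE),
        sourceId = sourceId(pair))
      deg <- .cropResizeOne(deg, w, outSide, TRUE)
    }
    x[, , , ri] <- composeInput(pair, deg, scheme)
    y[ri] <- manifest$true_iou[ri]
  }
  list(x = x, y = y)
}

#' Read or write a dataset manifest CSV
#'
#' The on-disk format has the fixed header
#' \code{sample_id,source_id,mask_path,true_iou,bin,seed}.
#'
#' @param manifest manifest \code{data.frame}.
#' @param path CSV path.
#' @return \code{readManifest}: the manifest; \code{writeManifest}: the
#'   path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  cols <- c("sample_id", "source_id", "mask_path", "true_iou", "bin", "seed")
  utils::write.csv(manifest[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
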