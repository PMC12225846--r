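#' @include artifact-generator.R
NULL

#' Read or write a corruption configuration as YAML
#'
#' The YAML layout mirrors the [CorruptionConfig-class] slots, e.g.
#' \preformatted{
#' pApply: {scaling: 0.5, borderFuzz: 0.5, smallArtifacts: 0.5, largeArtifacts: 0.5}
#' scalingIterationsRange: [1, 5]
#' edgeFlipProbability: 0.5
#' }
#' Missing fields fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return \code{readCorruptionConfig}: a [CorruptionConfig-class];
#'   \code{writeCorruptionConfig}: the path, invisibly.
#' @export
readCorruptionConfig <- function(path) {
  y <- yaml::read_yaml(path)
  def <- corruptionConfig()
  pA <- def@pApply
  if (!is.null(y$pApply)) pA[names(y$pApply)] <- unlist(y$pApply)
  pick <- function(nm, fallback) if (is.null(y[[nm]])) fallback else y[[nm]]
  corruptionConfig(
    pApply = pA,
    scalingIterationsRange = pick("scalingIterationsRange",
                                  def@scalingIterationsRange),
    edgeFlipProbability = pick("edgeFlipProbability",
                               def@edgeFlipProbability),
    maxSpheres = pick("maxSpheres", def@maxSpheres),
    sphereRadiusRange = pick("sphereRadiusRange", def@sphereRadiusRange),
    sphereProximity = pick("sphereProximity", def@sphereProximity),
    perlinPeriodsRange = pick("perlinPeriodsRange",
                              def@perlinPeriodsRange),
    perlinThresholdRange = pick("perlinThresholdRange",
                                def@perlinThresholdRange),
    perlinMode = pick("perlinMode", def@perlinMode))
}

#' @rdname readCorruptionConfig
#' @param cfg a [CorruptionConfig-class].
#' @export
writeCorruptionConfig <- function(cfg, path) {
  yaml::write_yaml(list(
    pApply = as.list(cfg@pApply),
    scalingIterationsRange = cfg@scalingIterationsRange,
    edgeFlipProbability = cfg@edgeFlipProbability,
    maxSpheres = cfg@maxSpheres,
    sphereRadiusRange = cfg@sphereRadiusRange,
    sphereProximity = cfg@sphereProximity,
    perlinPeriodsRange = cfg@perlinPeriodsRange,
    perlinThresholdRange = cfg@perlinThresholdRange,
    perlinMode = cfg@perlinMode), path)
  invisible(path)
}

#' Corrupt a directory of ground-truth masks
#'
#' Reads every PNG mask in \code{masksDir}, degrades each
#' \code{perMask} times with [degradeMask()], writes the degraded masks
#' as PNGs into \code{outDir}, and returns (and optionally writes) a
#' manifest with the true IoU and the applied corruption steps serialized
#' as JSON.
#'
#' @param masksDir directory of input mask PNGs.
#' @param outDir output directory (created if missing).
#' @param cfg a [CorruptionConfig-class].
#' @param seed master seed.
#' @param perMask degraded variants per input mask.
#' @param manifestPath optional CSV path for the manifest.
#' @return \code{data.frame} with columns \code{filename},
#'   \code{source}, \code{true_iou}, \code{seed}, \code{applied_steps}.
#' @export
corruptMaskDir <- function(masksDir, outDir, cfg = corruptionConfig(),
                           seed, perMask = 1L, manifestPath = NULL) {
  files <- sort(list.files(masksDir, pattern = "\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop(sprintf("no PNG masks found in %s", masksDir))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  rows <- list()
  .withSeed(as.integer(seed), {
    for (f in files) {
      m <- readMaskPNG(f)
      base <- sub("\\.png$", "", basename(f))
      for (v in seq_len(perMask)) {
        sd <- sample.int(2147483646L, 1L)
        ds <- degradeMask(m, cfg, sd)
        out <- sprintf("%s_deg%02d.png", base, v)
        writeMaskPNG(degradedMask(ds), file.path(outDir, out))
        rows[[length(rows) + 1L]] <- data.frame(
          filename = out, source = basename(f), true_iou = trueIoU(ds),
          seed = sd,
          applied_steps = as.character(jsonlite::toJSON(
            appliedSteps(ds), auto_unbox = TRUE, digits = NA)),
          stringsAsFactors = FALSE)
      }
    }
  })
  man <- do.call(rbind, rows)
  if (!is.null(manifestPath)) {
    utils::write.csv(man, manifestPath, row.names = FALSE)
  }
  man
}

#' Read a rater annotation directory tree
#'
#' Expects the layout \code{rater_<i>/round_<r>/<image>.png} with
#' identical image file names in every round folder.
#'
#' @param dir root directory.
#' @return A [RaterAnnotationSet-class].
#' @export
readRaterTree <- function(dir) {
  raters <- sort(list.dirs(dir, recursive = FALSE))
  raters <- raters[grepl("rater_", basename(raters))]
  if (!length(raters)) stop(sprintf("no rater_<i> directories in %s", dir))
  masks <- lapply(raters, function(rd) {
    rounds <- sort(list.dirs(rd, recursive = FALSE))
    rounds <- rounds[grepl("round_", basename(rounds))]
    imgs <- sort(list.files(rounds[1], pattern = "\\.png$"))
    lapply(imgs, function(img) {
      lapply(rounds, function(rnd) readMaskPNG(file.path(rnd, img)))
    })
  })
  raterAnnotationSet(masks)
}

#' Write a rater annotation set as a directory tree
#'
#' Inverse of [readRaterTree()].
#'
#' @param set a [RaterAnnotationSet-class].
#' @param dir root directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeRaterTree <- function(set, dir) {
  for (i in seq_len(nRaters(set))) {
    for (r in seq_len(nRounds(set))) {
      d <- file.path(dir, sprintf("rater_%d", i), sprintf("round_%d", r))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_len(nImages(set))) {
        writeMaskPNG(raterMask(set, i, k, r),
                     file.path(d, sprintf("image_%03d.png", k)))
      }
    }
  }
  invisible(dir)
}
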