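#' @include AllClasses.R dataset-builder.R
#' @useDynLib glottisQC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.backbones <- new.env(parent = emptyenv())

#' Register a convolutional backbone
#'
#' A backbone is a named recipe for the feature extractor in front of the
#' fixed regression head. A recipe is a function of the input side
#' returning \code{list(channels = integer vector)}: one 3x3-conv + ReLU +
#' 2x2-max-pool block per entry. The bundled \code{"tiny"} backbone is a
#' 4-block net sized for 64 px inputs; heavier ImageNet-class backbones
#' can be plugged in by registering wider/deeper recipes under their own
#' names.
#'
#' @param name backbone name.
#' @param recipe function(inputSide) -> list(channels = integer()).
#' @return the name, invisibly.
#' @export
registerBackbone <- function(name, recipe) {
  stopifnot(is.character(name), is.function(recipe))
  assign(name, recipe, envir = .backbones)
  invisible(name)
}

#' @rdname registerBackbone
#' @export
listBackbones <- function() sort(ls(.backbones))

.getBackbone <- function(name) {
  if (!exists(name, envir = .backbones, inherits = FALSE)) {
    stop(sprintf("unknown backbone '%s'; registered backbones: %s",
                 name, paste(listBackbones(), collapse = ", ")))
  }
  get(name, envir = .backbones, inherits = FALSE)
}

# registered at load time; see zzz.R
.tinyRecipe <- function(inputSide) list(channels = c(8L, 16L, 32L, 48L))

#' Build an IoU regression model
#'
#' Assembles the named backbone (a stack of 3x3-conv/ReLU/max-pool blocks)
#' and the fixed head: GlobalAveragePooling, Dense(256, ReLU),
#' Dropout(0.1), Dense(1, sigmoid). Weights are He-initialized from the
#' given seed, so two builds with the same seed produce identical initial
#' predictions.
#'
#' @param backbone registered backbone name (see [listBackbones()]).
#' @param inputSide square input side; must be divisible by \code{2^depth}
#'   of the backbone.
#' @param seed integer seed for weight initialization.
#' @param loss training loss: \code{"bce"} (cross-entropy against the IoU
#'   as a soft label; default), \code{"mse"} or \code{"mae"}.
#' @return an [IoURegressor-class].
#' @examples
#' m <- buildModel("tiny", inputSide = 64, seed = 1)
#' headLayers(m)
#' @export
buildModel <- function(backbone = "tiny", inputSide = 64L, seed = 1L,
                       loss = c("bce", "mse", "mae")) {
  loss <- match.arg(loss)
  inputSide <- as.integer(inputSide)
  recipe <- .getBackbone(backbone)(inputSide)
  ch <- as.integer(recipe$channels)
  if (inputSide %% (2^length(ch)) != 0L) {
    stop(sprintf("inputSide %d not divisible by 2^%d (backbone depth)",
                 inputSide, length(ch)))
  }
  params <- .withSeed(as.integer(seed), {
    convW <- list(); convB <- list()
    cin <- 3L
    for (l in seq_along(ch)) {
      fanIn <- 9L * cin
      convW[[l]] <- matrix(stats::rnorm(ch[l] * fanIn, 0,
                                        sqrt(2 / fanIn)), ch[l], fanIn)
      convB[[l]] <- numeric(ch[l])
      cin <- ch[l]
    }
    nFeat <- ch[length(ch)]
    list(convW = convW, convB = convB,
         fcW1 = matrix(stats::rnorm(256L * nFeat, 0, sqrt(2 / nFeat)),
                       256L, nFeat),
         fcb1 = numeric(256L),
         fcW2 = matrix(stats::rnorm(256L, 0, sqrt(1 / 256)), 1L, 256L),
         fcb2 = numeric(1L))
  })
  layers <- c(sprintf("Conv3x3(%d)+ReLU+MaxPool2", ch),
              "GlobalAveragePooling2D", "Dense(256, ReLU)",
              "Dropout(0.1)", "Dense(1, sigmoid)")
  new("IoURegressor", backbone = backbone, inputSide = inputSide,
      params = params, layers = layers, loss = loss)
}

#' Build a training specification
#'
#' @param optimizer \code{"adam"} (initial learning rate 1e-3) or
#'   \code{"sgd_momentum"} (momentum 0.9, initial learning rate 1e-2).
#' @param lr initial learning rate; defaults to the optimizer's standard
#'   value.
#' @param momentum SGD momentum.
#' @param epochs training epochs.
#' @param decayAfter epoch after which the learning rate decays.
#' @param decayRate exponential decay rate.
#' @param decayMode \code{"per_epoch"}: multiply by \code{exp(-decayRate)}
#'   every epoch past \code{decayAfter} (default); \code{"one_time"}:
#'   apply the factor once.
#' @param loss \code{"bce"}, \code{"mse"} or \code{"mae"}.
#' @param batchSize minibatch size.
#' @param dropout dropout probability in the head.
#' @return a \code{trainSpec} list.
#' @export
trainSpec <- function(optimizer = c("adam", "sgd_momentum"), lr = NULL,
                      momentum = 0.9, epochs = 50L, decayAfter = 10L,
                      decayRate = 0.1,
                      decayMode = c("per_epoch", "one_time"),
                      loss = c("bce", "mse", "mae"), batchSize = 32L,
                      dropout = 0.1) {
  optimizer <- match.arg(optimizer)
  decayMode <- match.arg(decayMode)
  loss <- match.arg(loss)
  if (is.null(lr)) lr <- if (optimizer == "adam") 1e-3 else 1e-2
  if (lr <= 0) stop("lr must be > 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(optimizer = optimizer, lr = lr, momentum = momentum,
                 epochs = as.integer(epochs),
                 decayAfter = as.integer(decayAfter),
                 decayRate = decayRate, decayMode = decayMode,
                 loss = loss, batchSize = as.integer(batchSize),
                 dropout = dropout),
            class = "trainSpec")
}

#' Learning rate at a given epoch
#'
#' The rate stays at its initial value through epoch \code{decayAfter} and
#' is then reduced by the factor \eqn{e^{-decayRate}}; in
#' \code{"per_epoch"} mode the factor compounds each epoch past the
#' plateau, in \code{"one_time"} mode it is applied once.
#'
#' @param spec a [trainSpec()].
#' @param epoch epoch number (1-based).
#' @return numeric learning rate.
#' @examples
#' lrAtEpoch(trainSpec("adam"), 11)  # 1e-3 * exp(-0.1)
#' @export
lrAtEpoch <- function(spec, epoch) {
  if (epoch <= spec$decayAfter) return(spec$lr)
  if (spec$decayMode == "one_time") return(spec$lr * exp(-spec$decayRate))
  spec$lr * exp(-spec$decayRate * (epoch - spec$decayAfter))
}

.forwardBatch <- function(params, x, y = NULL, loss = "bce",
                          dropMask = NULL, wantGrad = FALSE) {
  .tinyNetPass(x, params$convW, params$convB, params$fcW1, params$fcb1,
               params$fcW2, params$fcb2,
               if (is.null(dropMask)) matrix(0, 0, 0) else dropMask,
               if (is.null(y)) numeric(0) else y,
               loss, wantGrad)
}

# flatten/unflatten parameter lists for generic optimizer updates
.paramNames <- function(params) {
  c(sprintf("convW%d", seq_along(params$convW)),
    sprintf("convB%d", seq_along(params$convB)),
    "fcW1", "fcb1", "fcW2", "fcb2")
}
.getParam <- function(params, nm) {
  if (grepl("^convW", nm)) params$convW[[as.integer(sub("convW", "", nm))]]
  else if (grepl("^convB", nm)) params$convB[[as.integer(sub("convB", "", nm))]]
  else params[[nm]]
}
.setParam <- function(params, nm, val) {
  if (grepl("^convW", nm)) params$convW[[as.integer(sub("convW", "", nm))]] <- val
  else if (grepl("^convB", nm)) params$convB[[as.integer(sub("convB", "", nm))]] <- val
  else params[[nm]] <- val
  params
}
.getGrad <- function(res, nm) {
  if (grepl("^convW", nm)) res$gradConvW[[as.integer(sub("convW", "", nm))]]
  else if (grepl("^convB", nm)) res$gradConvB[[as.integer(sub("convB", "", nm))]]
  else res[[paste0("grad", toupper(substring(nm, 1, 1)),
                   substring(nm, 2))]]
}

#' Train an IoU regressor
#'
#' Minibatch gradient training with the configured optimizer, loss and
#' learning-rate schedule. Per-epoch train and validation losses are
#' recorded and the parameters with the best validation loss are returned
#' (last epoch when no validation set is given). Fully deterministic for a
#' fixed \code{(model, data, spec, seed)}.
#'
#' @param model an untrained [IoURegressor-class].
#' @param x \code{H x W x 3 x N} input array (see
#'   [makeRegressionTensors()]).
#' @param y numeric vector of true IoU targets.
#' @param valX,valY optional validation tensors.
#' @param spec a [trainSpec()]; its loss overrides the model's.
#' @param seed integer seed driving shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return the trained [IoURegressor-class] with its history filled in.
#' @export
trainRegressor <- function(model, x, y, valX = NULL, valY = NULL,
                           spec = trainSpec(), seed = 1L,
                           verbose = FALSE) {
  n <- dim(x)[4]
  if (!n || length(y) != n) stop("x and y sizes disagree")
  params <- model@params
  nms <- .paramNames(params)
  opt <- new.env(parent = emptyenv())
  for (nm in nms) {
    z <- .getParam(params, nm) * 0
    assign(paste0("v_", nm), z, envir = opt)   # momentum / adam m
    assign(paste0("s_", nm), z, envir = opt)   # adam v
  }
  adamT <- 0L
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     trainLoss = numeric(), valLoss = numeric())
  best <- list(loss = Inf, params = params)
  .withSeed(as.integer(seed), {
    for (ep in seq_len(spec$epochs)) {
      lr <- lrAtEpoch(spec, ep)
      ord <- sample.int(n)
      epLoss <- 0; seen <- 0L
      for (start in seq(1L, n, by = spec$batchSize)) {
        idx <- ord[start:min(start + spec$batchSize - 1L, n)]
        B <- length(idx)
        xb <- x[, , , idx, drop = FALSE]
        dm <- matrix(stats::rbinom(256L * B, 1L, 1 - spec$dropout) /
                       (1 - spec$dropout), 256L, B)
        res <- .forwardBatch(params, xb, y[idx], spec$loss, dm,
                             wantGrad = TRUE)
        if (!is.finite(res$loss)) {
          stop(sprintf(
            "training diverged: loss is %s at epoch %d (lr %.3g); try a lower learning rate",
            res$loss, ep, lr))
        }
        epLoss <- epLoss + res$loss * B; seen <- seen + B
        if (spec$optimizer == "sgd_momentum") {
          for (nm in nms) {
            v <- spec$momentum * get(paste0("v_", nm), opt) -
              lr * .getGrad(res, nm)
            assign(paste0("v_", nm), v, opt)
            params <- .setParam(params, nm, .getParam(params, nm) + v)
          }
        } else {
          adamT <- adamT + 1L
          b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
          for (nm in nms) {
            g <- .getGrad(res, nm)
            m1 <- b1 * get(paste0("v_", nm), opt) + (1 - b1) * g
            m2 <- b2 * get(paste0("s_", nm), opt) + (1 - b2) * g^2
            assign(paste0("v_", nm), m1, opt)
            assign(paste0("s_", nm), m2, opt)
            mh <- m1 / (1 - b1^adamT)
            vh <- m2 / (1 - b2^adamT)
            params <- .setParam(params, nm,
                                .getParam(params, nm) -
                                  lr * mh / (sqrt(vh) + eps))
          }
        }
      }
      trainLoss <- epLoss / seen
      valLoss <- NA_real_
      if (!is.null(valX)) {
        valLoss <- .forwardBatch(params, valX, valY, spec$loss)$loss
        if (valLoss < best$loss) best <- list(loss = valLoss,
                                              params = params)
      }
      hist[ep, ] <- list(ep, lr, trainLoss, valLoss)
      if (verbose) {
        message(sprintf("epoch %3d lr %.2e train %.4f val %s", ep, lr,
                        trainLoss,
                        ifelse(is.na(valLoss), "-",
                               sprintf("%.4f", valLoss))))
      }
    }
  })
  model@params <- if (is.finite(best$loss)) best$params else params
  model@loss <- spec$loss
  model@history <- hist
  model@trained <- TRUE
  model
}

#' Predict IoU for a batch of composed inputs
#'
#' @param model a trained [IoURegressor-class].
#' @param x \code{H x W x 3 x N} array.
#' @return numeric vector of predictions in (0, 1).
#' @export
predictBatch <- function(model, x) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (start in seq(1L, n, by = 256L)) {
    idx <- start:min(start + 255L, n)
    out[idx] <- .forwardBatch(model@params,
                              x[, , , idx, drop = FALSE])$pred
  }
  out
}

#' Predict the IoU of a candidate mask for one frame
#'
#' Preprocesses (crops around the candidate mask and resizes to the model
#' side), composes the scheme channels, and runs the forward pass.
#'
#' @param model a trained [IoURegressor-class].
#' @param image grayscale frame matrix in \[0, 255\] (or a
#'   [FramePair-class], whose image is used).
#' @param candidateMask binary mask from any segmentation source.
#' @param scheme channel scheme code (the deployment default is
#'   \code{"see"}).
#' @return predicted IoU in (0, 1).
#' @export
predictIoU <- function(model, image, candidateMask, scheme = "see") {
  if (is(image, "FramePair")) image <- frameImage(image)
  pair <- framePair(image, candidateMask)
  side <- model@inputSide
  if (nrow(image) != side || ncol(image) != side) {
    pair <- cropAndResize(pair, side)
  }
  x <- composeInput(pair, frameMask(pair), scheme)
  dim(x) <- c(dim(x), 1L)
  .forwardBatch(model@params, x)$pred[1]
}

#' Train and score one model per channel scheme
#'
#' Under identical seeds, data and budget, trains one fresh model per
#' scheme and reports its RMSE on the test manifest. Reruns with the same
#' arguments give identical tables.
#'
#' @param schemes character vector of scheme codes.
#' @param pairs ground-truth frame list.
#' @param trainManifest,valManifest,testManifest manifests from
#'   [splitManifest()] / [buildBalancedDataset()].
#' @param cfg the base [CorruptionConfig-class] of the manifests.
#' @param spec a [trainSpec()].
#' @param backbone,inputSide,seed model configuration shared by all runs.
#' @param binsSpec the [binSpec()] of the manifests.
#' @param anneal whether manifests were built with annealing.
#' @param verbose print progress.
#' @return \code{data.frame} with one row per scheme: scheme, test RMSE,
#'   Pearson correlation between predictions and true IoU.
#' @export
evaluateSchemes <- function(schemes, pairs, trainManifest, valManifest,
                            testManifest, cfg = corruptionConfig(),
                            spec = trainSpec(), backbone = "tiny",
                            inputSide = 64L, seed = 1L,
                            binsSpec = binSpec(), anneal = TRUE,
                            verbose = FALSE) {
  rows <- lapply(schemes, function(sc) {
    tr <- makeRegressionTensors(pairs, trainManifest, cfg, sc, inputSide,
                                binsSpec, anneal)
    va <- makeRegressionTensors(pairs, valManifest, cfg, sc, inputSide,
                                binsSpec, anneal)
    te <- makeRegressionTensors(pairs, testManifest, cfg, sc, inputSide,
                                binsSpec, anneal)
    model <- buildModel(backbone, inputSide, seed = seed)
    model <- trainRegressor(model, tr$x, tr$y, va$x, va$y, spec,
                            seed = seed, verbose = verbose)
    pred <- predictBatch(model, te$x)
    data.frame(scheme = sc, rmse = rmse(pred, te$y),
               pearson = stats::cor(pred, te$y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare per-model RMSE samples
#'
#' Shapiro-Wilk normality per group, then all pairwise two-sided
#' Mann-Whitney U tests with Bonferroni correction (the adjusted p-value
#' multiplies by the number of pairwise comparisons, capped at 1).
#'
#' @param samples named list of numeric vectors (e.g. per-frame squared
#'   errors or per-run RMSE values, one entry per model).
#' @param alpha significance level for the flags.
#' @return list with \code{normality} (data.frame: group, W, p),
#'   \code{pairwise} (data.frame: group1, group2, statistic, p, pAdjusted,
#'   significant), and \code{bonferroniFactor}.
#' @export
compareModels <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2L,
            !is.null(names(samples)))
  norm <- do.call(rbind, lapply(names(samples), function(nm) {
    x <- samples[[nm]]
    if (length(unique(x)) < 3L || length(x) < 3L) {
      return(data.frame(group = nm, W = NA_real_, p = NA_real_))
    }
    sw <- stats::shapiro.test(x)
    data.frame(group = nm, W = unname(sw$statistic), p = sw$p.value)
  }))
  prs <- utils::combn(names(samples), 2L)
  nPairs <- ncol(prs)
  pw <- do.call(rbind, lapply(seq_len(nPairs), function(ci) {
    g1 <- prs[1, ci]; g2 <- prs[2, ci]
    wt <- suppressWarnings(stats::wilcox.test(samples[[g1]],
                                              samples[[g2]],
                                              exact = FALSE))
    data.frame(group1 = g1, group2 = g2,
               statistic = unname(wt$statistic), p = wt$p.value)
  }))
  pw$pAdjusted <- stats::p.adjust(pw$p, method = "bonferroni")
  pw$significant <- pw$pAdjusted < alpha
  rownames(norm) <- rownames(pw) <- NULL
  list(normality = norm, pairwise = pw, bonferroniFactor = nPairs)
}
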