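# Three-branch multi-stream classifier: shared backbone architecture per
# branch, channel-level interaction at a configurable residual stage,
# 1x1 compression + concatenation fusion, and per-branch auxiliary heads.

#' Backbone architecture specification
#'
#' Four residual stages of bottleneck blocks with global average pooling.
#' The \code{"standard50"} variant is the canonical 50-layer residual
#' network (stages of 3/4/6/3 bottlenecks with widths 64/128/256/512,
#' 2048-channel stage-4 maps at 7x7 for 224x224 inputs). The
#' \code{"reduced"} variant keeps the four-stage bottleneck structure and
#' final pooling at desk scale (one block per stage, widths 8/16/32/64,
#' 64x64 inputs) for tests and synthetic benchmarks.
#'
#' @param variant "standard50" or "reduced".
#' @return list describing stem and stage layers, channel counts and the
#'   default input size.
#' @export
backboneArch <- function(variant = c("reduced", "standard50")) {
  variant <- match.arg(variant)
  if (variant == "standard50") {
    blocks <- c(3L, 4L, 6L, 3L); widths <- c(64L, 128L, 256L, 512L)
    stemOut <- 64L; input <- 224L
    stem <- list(convLayer("stem", 3L, stemOut, 7L, 2L, 3L),
                 bnLayer("stembn", stemOut), reluLayer(),
                 maxpoolLayer(3L, 2L, 1L))
  } else {
    blocks <- c(1L, 1L, 1L, 1L); widths <- c(8L, 16L, 32L, 64L)
    stemOut <- 16L; input <- 64L
    stem <- list(convLayer("stem", 3L, stemOut, 3L, 1L, 1L),
                 bnLayer("stembn", stemOut), reluLayer(),
                 maxpoolLayer(2L, 2L, 0L))
  }
  strides <- c(1L, 2L, 2L, 2L)
  stages <- vector("list", 4L)
  inC <- stemOut
  for (st in 1:4) {
    seg <- list()
    for (b in seq_len(blocks[st])) {
      seg[[b]] <- bottleneckLayer(sprintf("s%db%d", st, b), inC, widths[st],
                                  if (b == 1L) strides[st] else 1L)
      inC <- 4L * widths[st]
    }
    stages[[st]] <- seg
  }
  list(variant = variant, stem = stem, stages = stages,
       stageChannels = 4L * widths, outChannels = 4L * widths[4],
       defaultInput = input)
}

# Prefix every named layer of a segment so each branch owns its parameters.
prefixSegment <- function(segment, prefix) {
  lapply(segment, function(ly) {
    if (!is.null(ly$name)) ly$name <- paste0(prefix, ".", ly$name)
    ly
  })
}

#' Multi-stream peel classifier
#'
#' @slot branches input streams, a subset of c("whole", "exocarp",
#'   "albedo").
#' @slot variant backbone variant (see \code{\link{backboneArch}}).
#' @slot inputSize square input side in pixels fed to every branch.
#' @slot arch backbone architecture description.
#' @slot segments per-branch layer segments split at the interaction stage.
#' @slot interaction an \linkS4class{InteractionConfig}.
#' @slot fusion a \linkS4class{FusionConfig}.
#' @slot params flat named list of parameter arrays.
#' @slot classes class labels, in output order.
#' @export
setClass("MultiStreamModel",
         representation(branches = "character", variant = "character",
                        inputSize = "integer", arch = "list",
                        segments = "list", interaction = "InteractionConfig",
                        fusion = "FusionConfig", params = "list",
                        classes = "character"),
         validity = function(object) {
           if (!all(object@branches %in% c("whole", "exocarp", "albedo")))
             return("branches must be among whole/exocarp/albedo")
           if (anyDuplicated(object@branches))
             return("duplicate branch names")
           TRUE
         })

#' Create (and randomly initialize) a multi-stream model
#'
#' @param branches input streams; the full three-branch model uses
#'   \code{c("whole", "exocarp", "albedo")}; a single-input baseline uses
#'   e.g. \code{"whole"}.
#' @param variant backbone variant, "reduced" (default) or "standard50".
#' @param inputSize input side in pixels (defaults to the variant's
#'   standard input).
#' @param interaction an \linkS4class{InteractionConfig}; interaction is
#'   only applied when all three branches are present.
#' @param fusion a \linkS4class{FusionConfig}; by default compression is to
#'   512 channels for the standard backbone and 32 for the reduced one.
#' @param classes class labels in output order.
#' @param seed RNG seed for weight initialization.
#' @return a \linkS4class{MultiStreamModel}.
#' @export
multiStreamModel <- function(branches = c("whole", "exocarp", "albedo"),
                             variant = c("reduced", "standard50"),
                             inputSize = NULL,
                             interaction = interactionConfig(),
                             fusion = NULL,
                             classes = c("190", "560", "2800", "3300"),
                             seed = 1L) {
  variant <- match.arg(variant)
  arch <- backboneArch(variant)
  if (is.null(inputSize)) inputSize <- arch$defaultInput
  if (is.null(fusion)) {
    fusion <- fusionConfig(
      compressDim = if (variant == "standard50") 512L else 32L,
      nClasses = length(classes))
  }
  stage <- interaction@stage
  segments <- list()
  params <- withSeed(seed, {
    p <- list()
    for (br in branches) {
      pre <- prefixSegment(c(arch$stem, do.call(c, arch$stages[1:stage])), br)
      post <- if (stage < 4L)
        prefixSegment(do.call(c, arch$stages[(stage + 1L):4L]), br)
      else list()
      segments[[br]] <- list(pre = pre, post = post)
      p <- segmentInit(pre, p)
      p <- segmentInit(post, p)
      # 1x1 fusion compression per branch
      p <- segmentInit(list(convLayer(paste0("fuse.", br), arch$outChannels,
                                      fusion@compressDim, 1L, 1L, 0L)), p)
      if (length(branches) > 1L) {
        p[[paste0("aux.", br, ".W")]] <-
          matrix(stats::rnorm(fusion@nClasses * arch$outChannels,
                              sd = sqrt(1 / arch$outChannels)),
                 fusion@nClasses, arch$outChannels)
        p[[paste0("aux.", br, ".b")]] <- numeric(fusion@nClasses)
      }
    }
    fusedDim <- length(branches) * fusion@compressDim
    p[["head.W"]] <- matrix(stats::rnorm(fusion@nClasses * fusedDim,
                                         sd = sqrt(1 / fusedDim)),
                            fusion@nClasses, fusedDim)
    p[["head.b"]] <- numeric(fusion@nClasses)
    p
  })
  new("MultiStreamModel", branches = branches, variant = variant,
      inputSize = as.integer(inputSize), arch = arch, segments = segments,
      interaction = interaction, fusion = fusion, params = params,
      classes = classes)
}

setMethod("show", "MultiStreamModel", function(object) {
  cat(sprintf("MultiStreamModel (%s backbone, %d x %d input)\n",
              object@variant, object@inputSize, object@inputSize))
  cat("  branches:", paste(object@branches, collapse = ", "), "\n")
  cat(sprintf("  interaction: %s (stage %d, %.0f%%/%.0f%%)\n",
              if (object@interaction@active &&
                  length(object@branches) == 3L) "active" else "off",
              object@interaction@stage,
              100 * object@interaction@forwardRatio,
              100 * object@interaction@reverseRatio))
  cat(sprintf("  fusion: %d -> %d channels per branch, fused dim %d\n",
              object@arch$outChannels, object@fusion@compressDim,
              length(object@branches) * object@fusion@compressDim))
  cat(sprintf("  classes: %s\n", paste(object@classes, collapse = ", ")))
  cat(sprintf("  parameters: %s\n",
              format(length(paramsToVector(object@params)), big.mark = ",")))
})

#' @describeIn multiStreamModel current model parameters (flat named list)
#' @param model a \code{MultiStreamModel}
#' @export
modelParams <- function(model) model@params

#' @describeIn multiStreamModel replace model parameters
#' @param params flat named parameter list matching the model's shapes
#' @export
setModelParams <- function(model, params) {
  stopifnot(identical(names(params), names(model@params)))
  model@params <- params
  model
}

normalizeInput <- function(x) x / 127.5 - 1

zeroChannels <- function(x, idx) {
  if (length(idx) == 0L) return(x)
  if (length(dim(x)) == 3L) x[, , idx] <- 0 else x[, , idx, ] <- 0
  x
}

sliceAdd <- function(a, b, idx) {
  # a += b[channels idx] on those channels
  if (length(idx) == 0L) return(a)
  if (length(dim(a)) == 3L) a[, , idx] <- a[, , idx] + b[, , idx]
  else a[, , idx, ] <- a[, , idx, ] + b[, , idx, ]
  a
}

drawInteractionIndices <- function(model, train) {
  cfg <- model@interaction
  C <- model@arch$stageChannels[cfg@stage]
  draw <- function() list(
    fwd = sampleChannelIndices(C, cfg@forwardRatio),
    revE = sampleChannelIndices(C, cfg@reverseRatio),
    revA = sampleChannelIndices(C, cfg@reverseRatio))
  if (!train || cfg@freezeIndices) withSeed(cfg@seed, draw()) else draw()
}

# Full forward (and optional backward) pass of the multi-stream model.
# batch: list(x = named list of (h, w, 3, N) arrays, y = 1-based labels or
# NULL). Returns loss/probs and, when y is given and backward=TRUE, grads.
msForwardBackward <- function(model, params, batch, train = TRUE,
                              backward = !is.null(batch$y)) {
  branches <- model@branches
  interOn <- model@interaction@active && length(branches) == 3L
  keep <- backward
  pre <- list(); maps <- list()
  for (br in branches) {
    x <- normalizeInput(batch$x[[br]])
    pre[[br]] <- segmentForward(model@segments[[br]]$pre, params, x, keep)
    maps[[br]] <- pre[[br]]$out
  }
  idx <- NULL
  orig <- maps
  if (interOn) {
    idx <- drawInteractionIndices(model, train)
    Fm <- maps$whole; Em <- maps$exocarp; Am <- maps$albedo
    E2 <- replaceChannels(Em, Fm, idx$fwd)
    A2 <- replaceChannels(Am, Fm, idx$fwd)
    useOrig <- model@interaction@reverseUsesOriginal
    srcE <- if (useOrig) Em else E2
    srcA <- if (useOrig) Am else A2
    F1 <- replaceChannels(Fm, srcE, idx$revE)
    F2 <- replaceChannels(F1, srcA, idx$revA)
    maps <- list(whole = F2, exocarp = E2, albedo = A2)
  }
  post <- list(); feat <- list()
  for (br in branches) {
    post[[br]] <- segmentForward(model@segments[[br]]$post, params,
                                 maps[[br]], keep)
    feat[[br]] <- post[[br]]$out
  }
  # fusion: 1x1 compression + relu + GAP per branch, concatenation, linear
  fuse <- list(); vecs <- list()
  for (br in branches) {
    cv <- convForward(feat[[br]], params[[paste0("fuse.", br, ".W")]],
                      params[[paste0("fuse.", br, ".b")]], 1L, 0L, keep)
    rl <- reluForward(cv$out)
    gp <- gapForward(rl$out)
    fuse[[br]] <- list(cv = cv, rl = rl, gp = gp)
    vecs[[br]] <- gp$out
  }
  z <- do.call(rbind, vecs)
  lin <- linearForward(z, params[["head.W"]], params[["head.b"]])
  probs <- softmaxProbs(lin$out)

  aux <- list()
  useAux <- length(branches) > 1L && model@fusion@auxWeight > 0
  if (useAux) {
    for (br in branches) {
      gp <- gapForward(feat[[br]])
      al <- linearForward(gp$out, params[[paste0("aux.", br, ".W")]],
                          params[[paste0("aux.", br, ".b")]])
      aux[[br]] <- list(gp = gp, lin = al)
    }
  }

  if (is.null(batch$y)) {
    return(list(probs = probs, idx = idx))
  }
  y <- batch$y
  ceF <- softmaxCrossEntropy(lin$out, y)
  loss <- ceF$loss
  auxCE <- list()
  if (useAux) {
    for (br in branches) {
      auxCE[[br]] <- softmaxCrossEntropy(aux[[br]]$lin$out, y)
      loss <- loss + model@fusion@auxWeight * auxCE[[br]]$loss
    }
  }
  if (!backward) return(list(loss = loss, probs = probs, idx = idx))

  grads <- list()
  bh <- linearBackward(ceF$grad, params[["head.W"]], lin$cache)
  grads[["head.W"]] <- bh$dW
  grads[["head.b"]] <- bh$db
  cd <- model@fusion@compressDim
  dFeat <- list()
  for (i in seq_along(branches)) {
    br <- branches[i]
    dvec <- bh$dx[((i - 1L) * cd + 1L):(i * cd), , drop = FALSE]
    dgap <- gapBackward(dvec, fuse[[br]]$gp$cache)
    drl <- reluBackward(dgap, fuse[[br]]$rl$cache)
    bc <- convBackward(drl, params[[paste0("fuse.", br, ".W")]],
                       fuse[[br]]$cv$cache)
    grads[[paste0("fuse.", br, ".W")]] <- bc$dW
    grads[[paste0("fuse.", br, ".b")]] <- bc$db
    dFeat[[br]] <- bc$dx
    if (useAux) {
      dauxLogits <- model@fusion@auxWeight * auxCE[[br]]$grad
      ba <- linearBackward(dauxLogits, params[[paste0("aux.", br, ".W")]],
                           aux[[br]]$lin$cache)
      grads[[paste0("aux.", br, ".W")]] <- ba$dW
      grads[[paste0("aux.", br, ".b")]] <- ba$db
      dFeat[[br]] <- dFeat[[br]] + gapBackward(ba$dx, aux[[br]]$gp$cache)
    }
  }
  dMaps <- list()
  for (br in branches) {
    bk <- segmentBackward(model@segments[[br]]$post, params, dFeat[[br]],
                          post[[br]]$caches, grads)
    grads <- bk$grads
    dMaps[[br]] <- bk$dx
  }
  if (interOn) {
    useOrig <- model@interaction@reverseUsesOriginal
    dF2 <- dMaps$whole; dE2 <- dMaps$exocarp; dA2 <- dMaps$albedo
    dEm <- array(0, dim(dE2)); dAm <- array(0, dim(dA2))
    # reverse phase: F2 = Replace(Replace(F, srcE, revE), srcA, revA)
    if (useOrig) {
      dAm <- sliceAdd(dAm, dF2, idx$revA)
      dF1 <- zeroChannels(dF2, idx$revA)
      dEm <- sliceAdd(dEm, dF1, idx$revE)
      dFm <- zeroChannels(dF1, idx$revE)
    } else {
      dA2 <- sliceAdd(dA2, dF2, idx$revA)
      dF1 <- zeroChannels(dF2, idx$revA)
      dE2 <- sliceAdd(dE2, dF1, idx$revE)
      dFm <- zeroChannels(dF1, idx$revE)
    }
    # forward phase: E2/A2 take channels idx$fwd from F
    dFm <- sliceAdd(dFm, dE2, idx$fwd)
    dFm <- sliceAdd(dFm, dA2, idx$fwd)
    dEm <- dEm + zeroChannels(dE2, idx$fwd)
    dAm <- dAm + zeroChannels(dA2, idx$fwd)
    dMaps <- list(whole = dFm, exocarp = dEm, albedo = dAm)
  }
  for (br in branches) {
    bk <- segmentBackward(model@segments[[br]]$pre, params, dMaps[[br]],
                          pre[[br]]$caches, grads)
    grads <- bk$grads
  }
  grads <- grads[names(params)]
  list(loss = loss, probs = probs, grads = grads, idx = idx)
}

#' Loss-and-gradient closure for a model
#'
#' Returns \code{function(params, batch)} computing the (auxiliary-weighted)
#' cross-entropy loss and its gradient with respect to every parameter, for
#' use by the trainer and the meta-learning loops.
#'
#' @param model a \linkS4class{MultiStreamModel}.
#' @param train logical; whether interaction indices are resampled
#'   (training) or frozen to the config seed (evaluation).
#' @return closure returning \code{list(loss, grads)}.
#' @export
modelLossGrad <- function(model, train = TRUE) {
  force(model); force(train)
  function(params, batch) {
    r <- msForwardBackward(model, params, batch, train = train,
                           backward = TRUE)
    list(loss = r$loss, grads = r$grads)
  }
}

#' Run one backbone branch forward
#'
#' @param model a \linkS4class{MultiStreamModel}.
#' @param x input crop(s): (h, w, 3) or (h, w, 3, N), gray values 0--255.
#' @param branch which branch's parameters to use.
#' @param stopStage residual stage (1--4) whose activations to return; 4
#'   (default) yields the pre-pooling feature map.
#' @return feature map array (h', w', C, N).
#' @export
branchForward <- function(model, x, branch = model@branches[1],
                          stopStage = 4L) {
  stopifnot(branch %in% model@branches, stopStage %in% 1:4)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] != model@inputSize || dim(x)[2] != model@inputSize)
    stop("input must be ", model@inputSize, "x", model@inputSize)
  arch <- model@arch
  stage <- model@interaction@stage
  seg <- c(arch$stem, do.call(c, arch$stages[seq_len(stopStage)]))
  seg <- prefixSegment(seg, branch)
  segmentForward(seg, model@params, normalizeInput(x), keepCache = FALSE)$out
}

#' Fuse three stage-4 feature maps and classify
#'
#' Each map is compressed with the model's per-branch 1x1 convolution,
#' globally average-pooled, concatenated into the fused vector (length
#' 3 x compressDim for three branches) and projected to class probabilities
#' by the softmax head.
#'
#' @param model a \linkS4class{MultiStreamModel}.
#' @param maps named list of stage-4 feature maps, one per model branch,
#'   each (h, w, C) or (h, w, C, N).
#' @return list with \code{probs} (nClasses x N matrix, columns summing to
#'   1) and \code{fused} (the concatenated feature vector(s)).
#' @export
fuseAndClassify <- function(model, maps) {
  params <- model@params
  vecs <- lapply(model@branches, function(br) {
    m <- maps[[br]]
    if (is.null(m)) stop("missing map for branch ", br)
    if (length(dim(m)) == 3L) dim(m) <- c(dim(m), 1L)
    if (dim(m)[3] != model@arch$outChannels)
      stop("expected ", model@arch$outChannels, " channels, got ",
           dim(m)[3])
    cv <- convForward(m, params[[paste0("fuse.", br, ".W")]],
                      params[[paste0("fuse.", br, ".b")]], 1L, 0L, FALSE)
    gapForward(reluForward(cv$out)$out)$out
  })
  z <- do.call(rbind, vecs)
  logits <- linearForward(z, params[["head.W"]], params[["head.b"]])$out
  list(probs = softmaxProbs(logits), fused = z)
}

#' Cross-entropy classification loss
#'
#' \code{-sum(y * log(p))} for one-hot \code{y}, with a numerical floor of
#' 1e-12 on the probabilities.
#'
#' @param probs numeric vector of class probabilities (or a column matrix).
#' @param y one-hot vector of the same length.
#' @return scalar loss.
#' @examples
#' classificationLoss(rep(0.25, 4), c(1, 0, 0, 0))  # log(4)
#' @export
classificationLoss <- function(probs, y) {
  stopifnot(length(probs) == length(y))
  -sum(y * log(pmax(as.numeric(probs), 1e-12)))
}

#' End-to-end forward pass on one specimen
#'
#' @param model a three-branch \linkS4class{MultiStreamModel}.
#' @param whole,exocarp,albedo crops (h, w, 3), gray values 0--255, already
#'   at the model's input size.
#' @return named numeric vector of class probabilities.
#' @export
multiStreamForward <- function(model, whole, exocarp, albedo) {
  xs <- list(whole = whole, exocarp = exocarp, albedo = albedo)
  xs <- xs[model@branches]
  xs <- lapply(xs, function(x) { if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L); x })
  r <- msForwardBackward(model, model@params, list(x = xs, y = NULL),
                         train = FALSE)
  stats::setNames(as.numeric(r$probs), model@classes)
}

## ---- batching and prediction ----------------------------------------------

assembleBatch <- function(dataset, ids, branches) {
  xs <- lapply(branches, function(br) {
    arrs <- lapply(dataset@samples[ids], `[[`, br)
    d <- dim(arrs[[1]])
    out <- array(0, c(d, length(arrs)))
    for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
    out
  })
  names(xs) <- branches
  list(x = xs, y = as.integer(dataset@labels[ids]))
}

#' Predict class probabilities for a dataset
#'
#' @param model a \linkS4class{MultiStreamModel}.
#' @param dataset a \linkS4class{DomainDataset} with samples carrying the
#'   model's branches.
#' @param params optional parameter override (defaults to the model's).
#' @param batchSize mini-batch size for inference.
#' @return N x nClasses matrix of probabilities.
#' @export
predictProbs <- function(model, dataset, params = model@params,
                         batchSize = 32L) {
  n <- length(dataset)
  out <- matrix(NA_real_, n, model@fusion@nClasses)
  i <- 1L
  while (i <= n) {
    ids <- i:min(n, i + batchSize - 1L)
    b <- assembleBatch(dataset, ids, model@branches)
    r <- msForwardBackward(model, params, list(x = b$x, y = NULL),
                           train = FALSE)
    out[ids, ] <- t(r$probs)
    i <- i + batchSize
  }
  colnames(out) <- model@classes
  out
}

#' @describeIn predictProbs hard class predictions as a factor with the
#'   model's class levels
#' @export
predictClasses <- function(model, dataset, params = model@params,
                           batchSize = 32L) {
  p <- predictProbs(model, dataset, params, batchSize)
  factor(model@classes[max.col(p, ties.method = "first")],
         levels = model@classes)
}

#' Train a multi-stream model
#'
#' Mini-batch Adam with an optional cosine-annealed learning rate and early
#' stopping on validation accuracy.
#'
#' @param model a \linkS4class{MultiStreamModel}.
#' @param train a \linkS4class{DomainDataset} for training.
#' @param val optional validation \linkS4class{DomainDataset}.
#' @param epochs training epochs (default 80).
#' @param batchSize mini-batch size.
#' @param lr initial Adam learning rate (default 1e-4).
#' @param schedule "cosine" (default) or "constant".
#' @param patience early-stopping patience in epochs without validation
#'   improvement (ignored without \code{val}).
#' @param seed RNG seed controlling shuffling and interaction sampling.
#' @param verbose print per-epoch progress.
#' @return the model with trained parameters; training history (epoch,
#'   loss, validation accuracy) is attached as attribute
#'   \code{"history"} of the returned object's params.
#' @export
trainModel <- function(model, train, val = NULL, epochs = 80L,
                       batchSize = 16L, lr = 1e-4,
                       schedule = c("cosine", "constant"), patience = 10L,
                       seed = 1L, verbose = FALSE) {
  schedule <- match.arg(schedule)
  stopifnot(identical(levels(train@labels), model@classes))
  params <- model@params
  opt <- adamInit(params)
  n <- length(train)
  bestAcc <- -Inf; bestParams <- params; bad <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        valAcc = numeric(0))
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      lrEp <- if (schedule == "cosine") cosineLR(lr, ep, epochs) else lr
      ord <- sample.int(n)
      epLoss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batchSize)) {
        ids <- ord[start:min(n, start + batchSize - 1L)]
        b <- assembleBatch(train, ids, model@branches)
        r <- msForwardBackward(model, params, b, train = TRUE)
        st <- adamStep(params, r$grads, opt, lrEp)
        params <- st$params; opt <- st$state
        epLoss <- epLoss + r$loss; nb <- nb + 1L
      }
      vAcc <- NA_real_
      if (!is.null(val)) {
        pred <- predictClasses(model, val, params)
        vAcc <- mean(pred == val@labels)
        if (vAcc > bestAcc + 1e-9) {
          bestAcc <- vAcc; bestParams <- params; bad <- 0L
        } else {
          bad <- bad + 1L
        }
      }
      history[nrow(history) + 1L, ] <- list(ep, epLoss / nb, vAcc)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val acc %s", ep,
                        epLoss / nb,
                        if (is.na(vAcc)) "-" else sprintf("%.3f", vAcc)))
      if (!is.null(val) && bad >= patience) break
      if (!is.null(val) && bestAcc >= 1 - 1e-12) break
    }
  })
  finalParams <- if (!is.null(val)) bestParams else params
  attr(finalParams, "history") <- history
  setModelParams(model, finalParams)
}
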