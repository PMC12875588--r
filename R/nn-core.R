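# Minimal convolutional-network engine used by the multi-stream classifier.
#
# Feature blocks are dense arrays with dim (H, W, C, N); parameters live in a
# flat named list so the meta-learning code can treat a whole model as a
# single point in parameter space. Convolutions go through im2col (C++) plus
# one BLAS matrix product; every primitive has an explicit backward pass.

## ---- primitives -----------------------------------------------------------

convForward <- function(x, W, b, stride = 1L, pad = 0L, keepCache = TRUE) {
  d <- dim(x)
  k <- dim(W)[1]
  outC <- dim(W)[4]
  stopifnot(dim(W)[3] == d[3])
  col <- .cpp_im2col(x, d[1], d[2], d[3], d[4], k, stride, pad)
  oh <- (d[1] + 2L * pad - k) %/% stride + 1L
  ow <- (d[2] + 2L * pad - k) %/% stride + 1L
  Wmat <- matrix(W, nrow = k * k * d[3])
  outMat <- crossprod(Wmat, col) + b
  dim(outMat) <- c(outC, oh, ow, d[4])
  out <- aperm(outMat, c(2, 3, 1, 4))
  cache <- if (keepCache) {
    list(col = col, dimX = d, k = k, stride = stride, pad = pad,
         dimW = dim(W))
  }
  list(out = out, cache = cache)
}

convBackward <- function(dout, W, cache) {
  d <- cache$dimX
  k <- cache$k
  outC <- cache$dimW[4]
  dmat <- aperm(dout, c(3, 1, 2, 4))
  dim(dmat) <- c(outC, length(dmat) %/% outC)
  dW <- cache$col %*% t(dmat)
  dim(dW) <- cache$dimW
  db <- rowSums(dmat)
  Wmat <- matrix(W, nrow = k * k * d[3])
  dcol <- Wmat %*% dmat
  dx <- .cpp_col2im(dcol, d[1], d[2], d[3], d[4], k, cache$stride, cache$pad)
  list(dx = dx, dW = dW, db = db)
}

reluForward <- function(x) {
  out <- x
  out[out < 0] <- 0
  list(out = out, cache = out)
}

reluBackward <- function(dout, cache) dout * (cache > 0)

maxpoolForward <- function(x, k = 2L, stride = 2L, pad = 0L) {
  d <- dim(x)
  r <- .cpp_maxpool(x, d[1], d[2], d[3], d[4], k, stride, pad)
  list(out = r$out, cache = list(argmax = r$argmax, dimX = d))
}

maxpoolBackward <- function(dout, cache) {
  d <- cache$dimX
  .cpp_maxpool_bwd(dout, cache$argmax, d[1], d[2], d[3], d[4])
}

# Batch normalization over (h, w, N) per channel, using batch statistics in
# every mode (the transductive convention common in meta-learning, which
# keeps the model a pure function of its parameters).
bnForward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  xp <- aperm(x, c(1, 2, 4, 3))
  dim(xp) <- c(d[1] * d[2] * d[4], d[3])
  m <- colMeans(xp)
  xc <- sweep(xp, 2, m, "-")
  v <- colMeans(xc * xc)
  invStd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, invStd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(out) <- c(d[1], d[2], d[4], d[3])
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out, cache = list(xhat = xhat, invStd = invStd, dimX = d))
}

bnBackward <- function(dout, gamma, cache) {
  d <- cache$dimX
  n <- d[1] * d[2] * d[4]
  dp <- aperm(dout, c(1, 2, 4, 3))
  dim(dp) <- c(n, d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dp * xhat)
  dbeta <- colSums(dp)
  dxhat <- sweep(dp, 2, gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
  t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
  dx <- sweep(t1 - t2, 2, cache$invStd, "*")
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dx, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

gapForward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  out <- matrix(colMeans(m), d[3], d[4])
  list(out = out, cache = d)
}

gapBackward <- function(dout, cache) {
  d <- cache
  dx <- array(rep(as.numeric(dout), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  dx
}

linearForward <- function(x, W, b) {
  list(out = W %*% x + b, cache = x)
}

linearBackward <- function(dout, W, cache) {
  list(dx = crossprod(W, dout), dW = tcrossprod(dout, cache), db = rowSums(dout))
}

softmaxProbs <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Mean cross-entropy over a batch; y are 1-based class indices.
softmaxCrossEntropy <- function(logits, y) {
  p <- softmaxProbs(logits)
  n <- ncol(p)
  idx <- cbind(y, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  grad <- p
  grad[idx] <- grad[idx] - 1
  list(loss = loss, grad = grad / n, probs = p)
}

## ---- layer/segment framework ---------------------------------------------

convLayer <- function(name, inC, outC, k, stride = 1L, pad = 0L)
  list(type = "conv", name = name, inC = inC, outC = outC, k = k,
       stride = stride, pad = pad)
reluLayer <- function() list(type = "relu")
bnLayer <- function(name, C) list(type = "bn", name = name, C = C)
maxpoolLayer <- function(k, stride, pad = 0L)
  list(type = "maxpool", k = k, stride = stride, pad = pad)
bottleneckLayer <- function(name, inC, width, stride = 1L)
  list(type = "bottleneck", name = name, inC = inC, width = width,
       stride = stride, outC = 4L * width)

#' @noRd
segmentInit <- function(segment, params = list()) {
  heConv <- function(k, inC, outC) {
    array(stats::rnorm(k * k * inC * outC, sd = sqrt(2 / (k * k * inC))),
          dim = c(k, k, inC, outC))
  }
  bnPair <- function(params, name, C) {
    params[[paste0(name, ".gamma")]] <- rep(1, C)
    params[[paste0(name, ".beta")]] <- numeric(C)
    params
  }
  for (ly in segment) {
    if (ly$type == "conv") {
      params[[paste0(ly$name, ".W")]] <- heConv(ly$k, ly$inC, ly$outC)
      params[[paste0(ly$name, ".b")]] <- numeric(ly$outC)
    } else if (ly$type == "bn") {
      params <- bnPair(params, ly$name, ly$C)
    } else if (ly$type == "bottleneck") {
      params[[paste0(ly$name, ".c1.W")]] <- heConv(1L, ly$inC, ly$width)
      params[[paste0(ly$name, ".c1.b")]] <- numeric(ly$width)
      params <- bnPair(params, paste0(ly$name, ".bn1"), ly$width)
      params[[paste0(ly$name, ".c2.W")]] <- heConv(3L, ly$width, ly$width)
      params[[paste0(ly$name, ".c2.b")]] <- numeric(ly$width)
      params <- bnPair(params, paste0(ly$name, ".bn2"), ly$width)
      params[[paste0(ly$name, ".c3.W")]] <- heConv(1L, ly$width, ly$outC)
      params[[paste0(ly$name, ".c3.b")]] <- numeric(ly$outC)
      params <- bnPair(params, paste0(ly$name, ".bn3"), ly$outC)
      if (ly$stride != 1L || ly$inC != ly$outC) {
        params[[paste0(ly$name, ".proj.W")]] <- heConv(1L, ly$inC, ly$outC)
        params[[paste0(ly$name, ".proj.b")]] <- numeric(ly$outC)
        params <- bnPair(params, paste0(ly$name, ".bnp"), ly$outC)
      }
    }
  }
  params
}

segmentForward <- function(segment, params, x, keepCache = TRUE) {
  caches <- if (keepCache) vector("list", length(segment))
  for (i in seq_along(segment)) {
    ly <- segment[[i]]
    if (ly$type == "conv") {
      r <- convForward(x, params[[paste0(ly$name, ".W")]],
                       params[[paste0(ly$name, ".b")]],
                       ly$stride, ly$pad, keepCache)
      x <- r$out
      if (keepCache) caches[[i]] <- r$cache
    } else if (ly$type == "relu") {
      r <- reluForward(x)
      x <- r$out
      if (keepCache) caches[[i]] <- r$cache
    } else if (ly$type == "bn") {
      r <- bnForward(x, params[[paste0(ly$name, ".gamma")]],
                     params[[paste0(ly$name, ".beta")]])
      x <- r$out
      if (keepCache) caches[[i]] <- r$cache
    } else if (ly$type == "maxpool") {
      r <- maxpoolForward(x, ly$k, ly$stride, ly$pad)
      x <- r$out
      if (keepCache) caches[[i]] <- r$cache
    } else if (ly$type == "bottleneck") {
      r <- bottleneckForward(ly, params, x, keepCache)
      x <- r$out
      if (keepCache) caches[[i]] <- r$cache
    } else {
      stop("unknown layer type: ", ly$type)
    }
  }
  list(out = x, caches = caches)
}

bottleneckForward <- function(ly, params, x, keepCache = TRUE) {
  nm <- ly$name
  c1 <- convForward(x, params[[paste0(nm, ".c1.W")]],
                    params[[paste0(nm, ".c1.b")]], 1L, 0L, keepCache)
  n1 <- bnForward(c1$out, params[[paste0(nm, ".bn1.gamma")]],
                  params[[paste0(nm, ".bn1.beta")]])
  r1 <- reluForward(n1$out)
  c2 <- convForward(r1$out, params[[paste0(nm, ".c2.W")]],
                    params[[paste0(nm, ".c2.b")]], ly$stride, 1L, keepCache)
  n2 <- bnForward(c2$out, params[[paste0(nm, ".bn2.gamma")]],
                  params[[paste0(nm, ".bn2.beta")]])
  r2 <- reluForward(n2$out)
  c3 <- convForward(r2$out, params[[paste0(nm, ".c3.W")]],
                    params[[paste0(nm, ".c3.b")]], 1L, 0L, keepCache)
  n3 <- bnForward(c3$out, params[[paste0(nm, ".bn3.gamma")]],
                  params[[paste0(nm, ".bn3.beta")]])
  hasProj <- !is.null(params[[paste0(nm, ".proj.W")]])
  sc <- if (hasProj) {
    pc <- convForward(x, params[[paste0(nm, ".proj.W")]],
                      params[[paste0(nm, ".proj.b")]], ly$stride, 0L,
                      keepCache)
    pn <- bnForward(pc$out, params[[paste0(nm, ".bnp.gamma")]],
                    params[[paste0(nm, ".bnp.beta")]])
    list(out = pn$out, cache = list(pc = pc$cache, pn = pn$cache))
  } else {
    list(out = x, cache = NULL)
  }
  rOut <- reluForward(n3$out + sc$out)
  cache <- if (keepCache) {
    list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache, c2 = c2$cache,
         n2 = n2$cache, r2 = r2$cache, c3 = c3$cache, n3 = n3$cache,
         sc = sc$cache, rOut = rOut$cache, hasProj = hasProj)
  }
  list(out = rOut$out, cache = cache)
}

bottleneckBackward <- function(ly, params, dout, cache, grads) {
  nm <- ly$name
  d <- reluBackward(dout, cache$rOut)
  bn3 <- bnBackward(d, params[[paste0(nm, ".bn3.gamma")]], cache$n3)
  grads[[paste0(nm, ".bn3.gamma")]] <- grads[[paste0(nm, ".bn3.gamma")]] %+0% bn3$dgamma
  grads[[paste0(nm, ".bn3.beta")]] <- grads[[paste0(nm, ".bn3.beta")]] %+0% bn3$dbeta
  b3 <- convBackward(bn3$dx, params[[paste0(nm, ".c3.W")]], cache$c3)
  grads[[paste0(nm, ".c3.W")]] <- grads[[paste0(nm, ".c3.W")]] %+0% b3$dW
  grads[[paste0(nm, ".c3.b")]] <- grads[[paste0(nm, ".c3.b")]] %+0% b3$db
  d2 <- reluBackward(b3$dx, cache$r2)
  bn2 <- bnBackward(d2, params[[paste0(nm, ".bn2.gamma")]], cache$n2)
  grads[[paste0(nm, ".bn2.gamma")]] <- grads[[paste0(nm, ".bn2.gamma")]] %+0% bn2$dgamma
  grads[[paste0(nm, ".bn2.beta")]] <- grads[[paste0(nm, ".bn2.beta")]] %+0% bn2$dbeta
  b2 <- convBackward(bn2$dx, params[[paste0(nm, ".c2.W")]], cache$c2)
  grads[[paste0(nm, ".c2.W")]] <- grads[[paste0(nm, ".c2.W")]] %+0% b2$dW
  grads[[paste0(nm, ".c2.b")]] <- grads[[paste0(nm, ".c2.b")]] %+0% b2$db
  d1 <- reluBackward(b2$dx, cache$r1)
  bn1 <- bnBackward(d1, params[[paste0(nm, ".bn1.gamma")]], cache$n1)
  grads[[paste0(nm, ".bn1.gamma")]] <- grads[[paste0(nm, ".bn1.gamma")]] %+0% bn1$dgamma
  grads[[paste0(nm, ".bn1.beta")]] <- grads[[paste0(nm, ".bn1.beta")]] %+0% bn1$dbeta
  b1 <- convBackward(bn1$dx, params[[paste0(nm, ".c1.W")]], cache$c1)
  grads[[paste0(nm, ".c1.W")]] <- grads[[paste0(nm, ".c1.W")]] %+0% b1$dW
  grads[[paste0(nm, ".c1.b")]] <- grads[[paste0(nm, ".c1.b")]] %+0% b1$db
  dx <- b1$dx
  if (cache$hasProj) {
    bnp <- bnBackward(d, params[[paste0(nm, ".bnp.gamma")]], cache$sc$pn)
    grads[[paste0(nm, ".bnp.gamma")]] <- grads[[paste0(nm, ".bnp.gamma")]] %+0% bnp$dgamma
    grads[[paste0(nm, ".bnp.beta")]] <- grads[[paste0(nm, ".bnp.beta")]] %+0% bnp$dbeta
    bp <- convBackward(bnp$dx, params[[paste0(nm, ".proj.W")]], cache$sc$pc)
    grads[[paste0(nm, ".proj.W")]] <- grads[[paste0(nm, ".proj.W")]] %+0% bp$dW
    grads[[paste0(nm, ".proj.b")]] <- grads[[paste0(nm, ".proj.b")]] %+0% bp$db
    dx <- dx + bp$dx
  } else {
    dx <- dx + d
  }
  list(dx = dx, grads = grads)
}

# accumulate-with-init helper: NULL-safe addition
`%+0%` <- function(a, b) if (is.null(a)) b else a + b

segmentBackward <- function(segment, params, dout, caches, grads = list()) {
  for (i in rev(seq_along(segment))) {
    ly <- segment[[i]]
    if (ly$type == "conv") {
      bk <- convBackward(dout, params[[paste0(ly$name, ".W")]], caches[[i]])
      grads[[paste0(ly$name, ".W")]] <- grads[[paste0(ly$name, ".W")]] %+0% bk$dW
      grads[[paste0(ly$name, ".b")]] <- grads[[paste0(ly$name, ".b")]] %+0% bk$db
      dout <- bk$dx
    } else if (ly$type == "relu") {
      dout <- reluBackward(dout, caches[[i]])
    } else if (ly$type == "bn") {
      bk <- bnBackward(dout, params[[paste0(ly$name, ".gamma")]], caches[[i]])
      grads[[paste0(ly$name, ".gamma")]] <- grads[[paste0(ly$name, ".gamma")]] %+0% bk$dgamma
      grads[[paste0(ly$name, ".beta")]] <- grads[[paste0(ly$name, ".beta")]] %+0% bk$dbeta
      dout <- bk$dx
    } else if (ly$type == "maxpool") {
      dout <- maxpoolBackward(dout, caches[[i]])
    } else if (ly$type == "bottleneck") {
      bk <- bottleneckBackward(ly, params, dout, caches[[i]], grads)
      grads <- bk$grads
      dout <- bk$dx
    }
  }
  list(dx = dout, grads = grads)
}

## ---- parameter-space helpers ----------------------------------------------

#' Flatten a named parameter list into one numeric vector
#' @param params named list of numeric arrays
#' @return numeric vector
#' @keywords internal
paramsToVector <- function(params) {
  unlist(params, use.names = FALSE)
}

#' Rebuild a parameter list from a flat vector using a template's shapes
#' @keywords internal
vectorToParams <- function(v, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    x <- v[(pos + 1L):(pos + n)]
    d <- dim(template[[nm]])
    if (!is.null(d)) dim(x) <- d
    out[[nm]] <- x
    pos <- pos + n
  }
  out
}

paramsAxpy <- function(params, grads, a) {
  for (nm in names(grads)) {
    params[[nm]] <- params[[nm]] + a * grads[[nm]]
  }
  params
}

## ---- Adam optimizer --------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Cosine-annealed learning rate over nEpochs, starting at lr0
cosineLR <- function(lr0, epoch, nEpochs) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / max(1, nEpochs)))
}

## ---- seeded evaluation helper ---------------------------------------------

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
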