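# Multi-stream model: backbone shapes, fusion head, losses, and the
# end-to-end forward/backward contract.

test_that("reduced backbone produces the configured stage shapes", {
  m <- multiStreamModel(branches = "whole", inputSize = 32L, seed = 2)
  x <- array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
  f4 <- branchForward(m, x, "whole", stopStage = 4L)
  expect_identical(dim(f4), c(2L, 2L, 256L, 1L))
  f2 <- branchForward(m, x, "whole", stopStage = 2L)
  expect_identical(dim(f2), c(8L, 8L, 64L, 1L))
  expect_identical(m@arch$stageChannels, c(32L, 64L, 128L, 256L))
  expect_error(branchForward(m, array(0, c(16, 16, 3)), "whole"), "32")
  # determinism: identical input, identical activations
  expect_identical(f4, branchForward(m, x, "whole", 4L))
})

test_that("classification loss matches the cross-entropy formula", {
  expect_equal(classificationLoss(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0)
  expect_equal(classificationLoss(rep(0.25, 4), c(0, 1, 0, 0)), log(4))
  p <- c(0.7, 0.1, 0.15, 0.05)
  expect_equal(classificationLoss(p, c(0, 0, 1, 0)), -log(0.15))
  # zero probability at the true class is floored, not infinite
  expect_lt(classificationLoss(c(1, 0, 0, 0), c(0, 1, 0, 0)), 28)
  expect_error(classificationLoss(c(0.5, 0.5), c(1, 0, 0)))
})

test_that("fusion head concatenates compressed branches and normalizes", {
  m <- multiStreamModel(inputSize = 32L, seed = 5)
  maps <- lapply(stats::setNames(m@branches, m@branches), function(b)
    array(rnorm(2 * 2 * 256), c(2, 2, 256)))
  r <- fuseAndClassify(m, maps)
  expect_identical(nrow(r$fused), 3L * m@fusion@compressDim)
  expect_equal(sum(r$probs), 1, tolerance = 1e-6)
  expect_true(all(r$probs >= 0))
  # zero classifier weights: uniform probabilities over 4 classes
  m@params[["head.W"]][] <- 0
  m@params[["head.b"]][] <- 0
  r0 <- fuseAndClassify(m, maps)
  expect_equal(as.numeric(r0$probs), rep(0.25, 4), tolerance = 1e-12)
  expect_error(fuseAndClassify(m, list(whole = array(0, c(2, 2, 8)))),
               "channels")
})

test_that("model forward is deterministic and probabilities normalize", {
  m <- multiStreamModel(inputSize = 32L, seed = 6)
  set.seed(60)
  crop <- function() array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
  w <- crop(); e <- crop(); a <- crop()
  p1 <- multiStreamForward(m, w, e, a)
  p2 <- multiStreamForward(m, w, e, a)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_named(p1, m@classes)
})

test_that("disabling interaction equals zero-ratio interaction", {
  mOn <- multiStreamModel(inputSize = 32L, seed = 8,
                          interaction = interactionConfig(
                            forwardRatio = 0, reverseRatio = 0))
  mOff <- multiStreamModel(inputSize = 32L, seed = 8,
                           interaction = interactionConfig(active = FALSE))
  set.seed(61)
  crop <- function() array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
  w <- crop(); e <- crop(); a <- crop()
  expect_equal(multiStreamForward(mOn, w, e, a),
               multiStreamForward(mOff, w, e, a))
})

test_that("the analytic gradient agrees with finite differences", {
  m <- multiStreamModel(inputSize = 16L, seed = 9)
  set.seed(90)
  xs <- lapply(stats::setNames(m@branches, m@branches), function(b)
    array(runif(16 * 16 * 3 * 3) * 255, c(16, 16, 3, 3)))
  batch <- list(x = xs, y = c(1L, 3L, 4L))
  lg <- modelLossGrad(m)
  r <- withSeed(17, lg(m@params, batch))
  expect_true(is.finite(r$loss))
  v <- paramsToVector(m@params)
  g <- paramsToVector(r$grads)
  expect_true(all(is.finite(g)))
  set.seed(91)
  for (i in sample(length(v), 4)) {
    eps <- 1e-5
    up <- v; up[i] <- up[i] + eps
    dn <- v; dn[i] <- dn[i] - eps
    lUp <- withSeed(17, lg(vectorToParams(up, m@params), batch))$loss
    lDn <- withSeed(17, lg(vectorToParams(dn, m@params), batch))$loss
    fd <- (lUp - lDn) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("parameter flattening round-trips shapes and values", {
  m <- multiStreamModel(branches = "whole", inputSize = 16L, seed = 10)
  v <- paramsToVector(m@params)
  back <- vectorToParams(v, m@params)
  expect_identical(back, m@params)
  v2 <- v; v2[5] <- 99
  expect_identical(paramsToVector(vectorToParams(v2, m@params)), v2)
})

test_that("the standard backbone yields 2048-channel 7x7 stage-4 maps", {
  m <- multiStreamModel(branches = "whole", variant = "standard50",
                        seed = 1)
  x <- array(runif(224 * 224 * 3) * 255, c(224, 224, 3))
  f <- branchForward(m, x, "whole", stopStage = 4L)
  expect_identical(dim(f), c(7L, 7L, 2048L, 1L))
  f2 <- branchForward(m, x, "whole", stopStage = 2L)
  expect_identical(dim(f2), c(28L, 28L, 512L, 1L))
  rm(m); gc(FALSE)
})
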