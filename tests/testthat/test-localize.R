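# Region localization: grayscale statistics, threshold rule, box
# refinement and the reference detector.

test_that("grayscale conversion uses luma weights and validates input", {
  white <- array(255, c(3, 3, 3))
  expect_equal(toGrayscale(white), matrix(255, 3, 3))
  black <- array(0, c(3, 3, 3))
  expect_equal(toGrayscale(black), matrix(0, 3, 3))
  one <- array(100, c(1, 1, 3))
  expect_equal(toGrayscale(one)[1, 1], 100)
  # weights act on distinct channels
  img <- array(0, c(1, 1, 3)); img[1, 1, 2] <- 200
  expect_equal(toGrayscale(img)[1, 1], 0.587 * 200)
  expect_error(toGrayscale(matrix(1, 3, 3)), "color")
  expect_error(toGrayscale(array(1, c(3, 3, 4))), "color")
})

test_that("global mean matches direct summation", {
  expect_equal(globalMean(matrix(c(10, 30, 20, 40), 2, 2)), 25)
  expect_equal(globalMean(matrix(7, 5, 9)), 7)
  expect_error(globalMean(matrix(numeric(0), 0, 0)), "empty")
  # disc fixture against an independent double-loop summation
  set.seed(31)
  g <- generatePeelImage(classProfiles()[["560"]], size = 64L)
  gray <- toGrayscale(g$image)
  acc <- 0
  for (i in seq_len(nrow(gray))) for (j in seq_len(ncol(gray)))
    acc <- acc + gray[i, j]
  expect_equal(globalMean(gray), acc / length(gray))
})

test_that("corner deviations follow the I(x, y) corner convention", {
  const <- matrix(42, 8, 8)
  expect_equal(unname(cornerDeviations(const, boundingBox(1, 1, 6, 6))),
               rep(0, 4))
  g <- matrix(100, 3, 3); g[1, 1] <- 0
  expect_equal(cornerDeviations(g, boundingBox(0, 0, 2, 2), mu = 100)[["TL"]],
               100)
  # non-square image: x indexes columns, y rows
  g2 <- matrix(0, 4, 6)  # H = 4, W = 6
  g2[2, 5] <- 50  # row 2 (y = 1), column 5 (x = 4)
  dev <- cornerDeviations(g2, boundingBox(1, 1, 4, 3), mu = 0)
  expect_equal(dev[["TR"]], 50)
  expect_equal(dev[["TL"]], 0)
  expect_error(cornerDeviations(g2, boundingBox(1, 1, 6, 3)), "bounds")
  # disc fixture: deviations match scalar pixel lookups
  set.seed(32)
  f <- generatePeelImage(classProfiles()[["190"]], size = 64L)
  gray <- toGrayscale(f$image)
  mu <- mean(gray)
  b <- f$albedoBox
  dev <- cornerDeviations(gray, b, mu)
  expect_equal(dev[["BR"]], abs(gray[b@y2 + 1, b@x2 + 1] - mu))
  expect_equal(dev[["BL"]], abs(gray[b@y2 + 1, b@x1 + 1] - mu))
})

test_that("deviation threshold is half the gray gap and symmetric", {
  expect_identical(computeThreshold(200, 160), 20)
  expect_identical(computeThreshold(130, 130), 0)
  expect_identical(computeThreshold(200, 169), 15.5)
  set.seed(33)
  for (i in 1:20) {
    a <- runif(1, 0, 255); b <- runif(1, 0, 255)
    expect_identical(computeThreshold(a, b), computeThreshold(b, a))
  }
  expect_error(computeThreshold(-1, 100))
})

test_that("refinement terminates immediately when corners already agree", {
  const <- matrix(128, 20, 20)
  r <- refineBox(const, boundingBox(2, 3, 15, 17),
                 refinementParams(tau = 5))
  expect_identical(boxCoords(r$box), boxCoords(boundingBox(2, 3, 15, 17)))
  expect_identical(r$iterations, 0L)
  expect_true(r$converged)
})

test_that("refinement shrinks a bright disc box like the scalar oracle", {
  # dark disc on a light background, luma gap 40, tau = 20, s = 1
  S <- 100L
  xs <- matrix(rep(0:(S - 1), each = S), S, S)
  ys <- matrix(rep(0:(S - 1), times = S), S, S)
  gray <- matrix(220, S, S)
  disc <- (xs - 50)^2 + (ys - 50)^2 <= 38^2
  gray[disc] <- 180
  r <- refineBox(gray, boundingBox(0, 0, S - 1, S - 1),
                 refinementParams(step = 1, tau = 20))
  o <- refineOracle(gray, 0L, 0L, S - 1L, S - 1L, s = 1L, tau = 20)
  expect_identical(boxCoords(r$box),
                   c(x1 = o$x1, y1 = o$y1, x2 = o$x2, y2 = o$y2))
  expect_identical(r$iterations, o$iterations)
  expect_identical(r$converged, o$converged)
  expect_true(r$converged)
  expect_true(all(cornerDeviations(gray, r$box) <= 20))
})

test_that("refinement is bit-identical to the oracle on random images", {
  set.seed(61)
  for (i in 1:120) {
    H <- sample(8:64, 1); W <- sample(8:64, 1)
    gray <- matrix(runif(H * W, 0, 255), H, W)
    x1 <- sample(0:(W - 4), 1); x2 <- sample((x1 + 2):(W - 1), 1)
    y1 <- sample(0:(H - 4), 1); y2 <- sample((y1 + 2):(H - 1), 1)
    tau <- runif(1, 0, 120)
    s <- sample(1:3, 1)
    r <- refineBox(gray, boundingBox(x1, y1, x2, y2),
                   refinementParams(step = s, tau = tau))
    o <- refineOracle(gray, x1, y1, x2, y2, s = s, tau = tau)
    expect_identical(boxCoords(r$box),
                     c(x1 = o$x1, y1 = o$y1, x2 = o$x2, y2 = o$y2))
    expect_identical(r$converged, o$converged)
    expect_identical(r$iterations, o$iterations)
    # shrink monotonicity: output contained in input
    expect_true(boxContains(boundingBox(x1, y1, x2, y2), r$box))
    # convergence semantics
    if (r$converged)
      expect_true(all(cornerDeviations(gray, r$box) <= tau))
  }
})

test_that("refinement halts on a hostile image instead of collapsing", {
  # every pixel far from the mean except one flat quadrant: the loop must
  # stop at the last valid box or the iteration cap, never error
  g <- matrix(rep(c(0, 255), each = 32), 8, 8)
  r <- refineBox(g, boundingBox(0, 0, 7, 7),
                 refinementParams(step = 3, tau = 1, maxIterations = 10))
  expect_false(r$converged)
  expect_true(validObject(r$box))
  expect_lte(r$iterations, 10L)
})

test_that("single-update mode moves a shared coordinate once per iteration", {
  # top corners both violate: default mode moves y1 by 2s, conservative by s
  g <- matrix(100, 12, 12)
  g[1, ] <- 250  # top row far from mean
  b <- boundingBox(0, 0, 11, 11)
  dflt <- refineBox(g, b, refinementParams(step = 1, tau = 60))
  cons <- refineBox(g, b, refinementParams(step = 1, tau = 60,
                                           singleUpdatePerCoordinate = TRUE))
  expect_identical(dflt$box@y1 - b@y1, 2L * dflt$iterations)
  expect_identical(cons$box@y1 - b@y1, 1L * cons$iterations)
})

test_that("the reference detector finds whole/exocarp/albedo regions", {
  set.seed(71)
  f <- generatePeelImage(classProfiles()[["2800"]], size = 96L)
  dets <- detectRegions(f$image)
  kinds <- vapply(dets, function(d) d@kind, "")
  expect_setequal(kinds, c("whole", "exocarp", "albedo"))
  whole <- dets[[which(kinds == "whole")]]
  albedo <- dets[[which(kinds == "albedo")]]
  expect_gte(boxIoU(whole@box, f$wholeBox), 0.5)
  expect_gte(boxIoU(albedo@box, f$albedoBox), 0.5)
})

test_that("a blank image yields an empty detection list, not a crash", {
  blank <- array(225, c(96, 96, 3))
  expect_warning(dets <- detectRegions(blank), "no regions")
  expect_length(dets, 0)
})

test_that("two specimens give two whole-specimen detections", {
  set.seed(72)
  a <- generatePeelImage(classProfiles()[["190"]], size = 80L)
  b <- generatePeelImage(classProfiles()[["3300"]], size = 80L)
  two <- array(225, c(80, 160, 3))
  two[, 1:80, ] <- a$image
  two[, 81:160, ] <- b$image
  dets <- detectRegions(two)
  kinds <- vapply(dets, function(d) d@kind, "")
  expect_identical(sum(kinds == "whole"), 2L)
})

test_that("localize-and-refine returns contained, converged boxes with crops", {
  set.seed(73)
  f <- generatePeelImage(classProfiles()[["560"]], size = 96L)
  res <- localizeAndRefine(f$image)
  expect_gt(length(res), 0)
  gray <- toGrayscale(f$image)
  for (r in res) {
    expect_true(boxContains(r$detected, r$box))
    if (r$converged)
      expect_true(all(cornerDeviations(gray, r$box) <= 20))
    expect_identical(dim(r$crop)[1], r$box@y2 - r$box@y1 + 1L)
    expect_identical(dim(r$crop)[2], r$box@x2 - r$box@x1 + 1L)
  }
})

test_that("bounding-box validity and geometry helpers", {
  expect_error(boundingBox(5, 0, 5, 10), "collapsed")
  expect_error(boundingBox(-1, 0, 5, 10), "non-negative")
  b1 <- boundingBox(0, 0, 9, 9); b2 <- boundingBox(5, 5, 14, 14)
  expect_equal(boxArea(b1), 100L)
  expect_equal(boxIoU(b1, b2), 25 / 175)
  expect_equal(boxIoU(b1, b1), 1)
  expect_true(boxContains(b1, boundingBox(2, 2, 7, 7)))
  expect_false(boxContains(b1, b2))
})
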