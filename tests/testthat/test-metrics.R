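# Evaluation metrics, repeated-run summaries, and comparison arithmetic.

test_that("metrics match hand-computed confusion arithmetic", {
  all <- computeMetrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(accuracy(all), 1)
  expect_equal(all@macroF1, 1)
  expect_equal(all@macroRecall, 1)
  # binary toy: TP=3, FP=1, FN=1, TN=5 for class "pos"
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  r <- computeMetrics(pred, truth)
  f1pos <- with(list(p = 3 / 4, rc = 3 / 4), 2 * p * rc / (p + rc))
  expect_equal(f1pos, 0.75)
  pcls <- 2 * (3 / 4) * (3 / 4) / (3 / 4 + 3 / 4)
  expect_equal(r@macroF1,
               mean(c(pcls, 2 * (5 / 6) * (5 / 6) / (5 / 6 + 5 / 6))))
  expect_equal(accuracy(r), 8 / 10)
  expect_identical(r@confusion["pos", "pos"], 3L)
  expect_identical(r@confusion["pos", "neg"], 1L)
  # confusion rows conserve per-class sample counts
  expect_identical(as.integer(rowSums(r@confusion)),
                   as.integer(table(factor(truth, levels = c("neg", "pos")))))
  expect_error(computeMetrics(character(0), character(0)), "empty")
  expect_error(computeMetrics(c("a"), c("a", "b")), "length")
})

test_that("metrics are invariant to sample order", {
  set.seed(44)
  truth <- sample(c("190", "560", "2800", "3300"), 60, replace = TRUE)
  pred <- sample(c("190", "560", "2800", "3300"), 60, replace = TRUE)
  perm <- sample(60)
  a <- computeMetrics(pred, truth)
  b <- computeMetrics(pred[perm], truth[perm])
  expect_equal(accuracy(a), accuracy(b))
  expect_identical(a@confusion, b@confusion)
})

test_that("a class absent from the labels warns and scores recall 0", {
  expect_warning(r <- computeMetrics(factor(c("a", "b", "c"),
                                            levels = c("a", "b", "c")),
                                     factor(c("a", "b", "b"),
                                            levels = c("a", "b", "c"))),
                 "absent")
  expect_equal(r@perClassAccuracy[["c"]], 0)
})

test_that("uniform random predictions sit at chance level", {
  set.seed(99)
  truth <- rep(c("190", "560", "2800", "3300"), each = 500)
  pred <- sample(c("190", "560", "2800", "3300"), 2000, replace = TRUE)
  expect_equal(accuracy(computeMetrics(pred, truth)), 0.25,
               tolerance = 0.05)
})

test_that("repeated runs summarize mean and sample deviation", {
  fixed <- repeatRuns(function(seed) 0.9, seeds = 1:5)
  expect_equal(fixed@mean, 0.9)
  expect_equal(fixed@sd, 0)
  two <- repeatRuns(function(seed) c(0.9, 1.0)[seed], seeds = 1:2)
  expect_equal(two@mean, 0.95)
  expect_equal(two@sd, sqrt((0.05^2 + 0.05^2) / 1), tolerance = 1e-12)
  expect_equal(two@sd, 0.0707107, tolerance = 1e-6)
  expect_identical(two@seeds, 1:2)
  # failed runs are warned about and excluded
  expect_warning(
    partial <- repeatRuns(function(seed) {
      if (seed == 2) stop("boom") else 0.5
    }, seeds = 1:3), "failed")
  expect_length(partial@values, 2)
  expect_error(repeatRuns(function(seed) 1, seeds = 1L), "length")
})

test_that("relative improvement reproduces the cross-domain arithmetic", {
  expect_equal(round(relativeImprovement(56.2, 75.4), 1), 34.2)
  expect_equal(round(relativeImprovement(52.5, 73.2), 1), 39.4)
  expect_equal(relativeImprovement(80, 80), 0)
  expect_error(relativeImprovement(0, 50), "positive")
  # sign behavior: degradation is negative, improvement positive
  expect_lt(relativeImprovement(80, 60), 0)
  expect_gt(relativeImprovement(60, 80), 0)
})

test_that("accuracy margins reproduce method-comparison arithmetic", {
  expect_equal(accuracyMargin(95.5, 94.3), 1.2)
  expect_equal(accuracyMargin(94.4, 85.1), 9.3)
  cmp <- compareMethods(c(ours = 95.5, densenet = 94.3, resnet = 85.1))
  expect_equal(cmp$margin[cmp$method == "densenet"], 1.2)
  expect_equal(cmp$margin[cmp$method == "ours"], 0)
})
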