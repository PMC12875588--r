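# Meta-learning: inner adaptation, second-order meta-gradients, task
# sampling and the adaptation/evaluation protocol.

test_that("inner adaptation follows the closed form on the quadratic family", {
  theta0 <- list(theta = 2)
  # alpha = 0: parameters unchanged
  expect_equal(innerAdapt(theta0, quadLossGrad, list(c = 0.5), 0, 3)$theta,
               theta0)
  # K = 1: theta - alpha * (theta - c)
  one <- innerAdapt(theta0, quadLossGrad, list(c = 0.5), 0.1, 1)
  expect_equal(one$theta$theta, 2 - 0.1 * 1.5)
  # K = 2: c + (1 - alpha)^2 (theta - c)
  two <- innerAdapt(theta0, quadLossGrad, list(c = 0.5), 0.1, 2)
  expect_equal(two$theta$theta, 0.5 + 0.9^2 * 1.5)
  # K = 5 iterated closed form
  five <- innerAdapt(theta0, quadLossGrad, list(c = -1), 0.2, 5)
  expect_equal(five$theta$theta, -1 + 0.8^5 * 3, tolerance = 1e-12)
  # the shared initialization is never mutated
  expect_identical(theta0$theta, 2)
  expect_length(two$trajectory, 2)
  expect_equal(two$trajectory[[1]]$theta, 2)
  # non-finite loss aborts
  expect_error(innerAdapt(list(theta = Inf), quadLossGrad, list(c = 0),
                          0.1, 1), "non-finite")
})

test_that("second-order meta-gradient matches the hand-derived form", {
  # L_s = (theta - c_s)^2 / 2, theta_K = c_s + (1 - a)^K (theta - c_s),
  # d L_q(theta_K) / d theta = (theta_K - c_q) (1 - a)^K
  for (case in list(list(a = 0.05, K = 3L, cs = 1, cq = -2, th = 2),
                    list(a = 0.3, K = 5L, cs = -0.7, cq = 0.4, th = 0.1))) {
    cfg <- metaConfig(innerRate = case$a, outerRate = 1,
                      innerSteps = case$K, order = "second")
    task <- list(support = list(c = case$cs), query = list(c = case$cq))
    up <- metaUpdate(list(theta = case$th), list(task), cfg, quadLossGrad)
    thK <- case$cs + (1 - case$a)^case$K * (case$th - case$cs)
    grad <- (thK - case$cq) * (1 - case$a)^case$K
    expect_equal(up$params$theta, case$th - grad,
                 tolerance = 1e-6 * max(1, abs(grad)))
  }
})

test_that("first-order approximation drops the inner-loop curvature term", {
  cfg1 <- metaConfig(innerRate = 0.1, outerRate = 1, innerSteps = 4L,
                     order = "first")
  task <- list(support = list(c = 1), query = list(c = 3))
  up <- metaUpdate(list(theta = 2), list(task), cfg1, quadLossGrad)
  thK <- 1 + 0.9^4 * 1
  expect_equal(up$params$theta, 2 - (thK - 3))
})

test_that("meta-updates aggregate tasks and move toward the family optimum", {
  cfg <- metaConfig(innerRate = 0.1, outerRate = 0.2, innerSteps = 3L)
  params <- list(theta = 0)
  set.seed(123)
  for (it in 1:60) {
    tasks <- lapply(1:4, function(i) {
      centre <- rnorm(1, mean = 5, sd = 0.2)
      list(support = list(c = centre), query = list(c = centre))
    })
    params <- metaUpdate(params, tasks, cfg, quadLossGrad)$params
  }
  # meta-trained initialization adapts faster than the naive start
  afterMeta <- innerAdapt(params, quadLossGrad, list(c = 5), 0.1, 1)
  afterNaive <- innerAdapt(list(theta = 0), quadLossGrad, list(c = 5), 0.1, 1)
  lossMeta <- quadLossGrad(afterMeta$theta, list(c = 5))$loss
  lossNaive <- quadLossGrad(afterNaive$theta, list(c = 5))$loss
  expect_lt(lossMeta, lossNaive)
  expect_lt(abs(params$theta - 5), 1)
})

test_that("episodic task sampling is stratified, disjoint and seeded", {
  ds <- tinyWorld()
  dom <- prepareSamples(ds, "deviceA", NULL, 24L, branches = "whole",
                        useDetector = FALSE, role = "source")
  cfg <- metaConfig(kShot = 5L, queryPerClass = 2L)
  set.seed(5)
  t1 <- sampleTask(dom, cfg)
  expect_length(t1$supportIds, 20)  # 4-way x 5-shot
  expect_length(t1$queryIds, 8)
  expect_length(intersect(t1$supportIds, t1$queryIds), 0)
  expect_true(all(table(dom@labels[t1$supportIds]) == 5))
  expect_true(all(table(dom@labels[t1$queryIds]) == 2))
  set.seed(5)
  t2 <- sampleTask(dom, cfg)
  expect_identical(t1$supportIds, t2$supportIds)
  # insufficient samples per class
  tiny <- domainDataset(dom@samples[1:6], dom@labels[1:6], "d", "source")
  expect_error(sampleTask(tiny, cfg), "fewer than")
})

test_that("direct transfer on the source distribution reproduces accuracy", {
  ds <- tinyWorld()
  tr <- prepareSamples(ds, "deviceA", "train", 24L,
                       branches = "whole", useDetector = FALSE)
  te <- prepareSamples(ds, "deviceA", c("val", "test"), 24L,
                       branches = "whole", useDetector = FALSE,
                       role = "target")
  m <- multiStreamModel(branches = "whole", inputSize = 24L, seed = 15)
  m <- trainModel(m, tr, epochs = 8L, batchSize = 8L, lr = 1e-3, seed = 15)
  rep1 <- directTransferEvaluate(m, te)
  expect_s4_class(rep1, "MetricsReport")
  expect_equal(accuracy(rep1),
               mean(predictClasses(m, te) == te@labels))
  expect_error(directTransferEvaluate(
    m, domainDataset(list(), factor(character()), "x", "target")), "empty")
  # adaptation protocol: reproducible mean/sd under fixed seeds
  cfg <- metaConfig(innerRate = 0.01, innerSteps = 2L, kShot = 1L)
  a1 <- adaptAndEvaluate(m, te, cfg, nRuns = 3L, seed = 77)
  a2 <- adaptAndEvaluate(m, te, cfg, nRuns = 3L, seed = 77)
  expect_identical(a1$runs, a2$runs)
  expect_equal(a1$summary@mean, mean(a1$runs))
  expect_equal(a1$summary@sd, sd(a1$runs))
})
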