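# Synthetic data generator: geometry, contrast calibration, device styles,
# manifests and splits.

test_that("peel images honor the configured contrast and geometry", {
  profs <- classProfiles()
  expect_named(profs, c("190", "560", "2800", "3300"))
  for (cl in names(profs)) {
    set.seed(200 + match(cl, names(profs)))
    f <- generatePeelImage(profs[[cl]], size = 96L, d = 40)
    expect_gte(f$gap, 35); expect_lte(f$gap, 45)
    expect_identical(dim(f$image), c(96L, 96L, 3L))
    expect_true(all(f$image >= 0 & f$image <= 255))
    # stored boxes equal the mask-derived bounds
    idx <- which(f$masks$specimen, arr.ind = TRUE)
    expect_identical(boxCoords(f$wholeBox),
                     c(x1 = min(idx[, 2]) - 1L, y1 = min(idx[, 1]) - 1L,
                       x2 = max(idx[, 2]) - 1L, y2 = max(idx[, 1]) - 1L))
    cdx <- which(f$masks$core, arr.ind = TRUE)
    expect_identical(boxCoords(f$albedoBox),
                     c(x1 = min(cdx[, 2]) - 1L, y1 = min(cdx[, 1]) - 1L,
                       x2 = max(cdx[, 2]) - 1L, y2 = max(cdx[, 1]) - 1L))
    expect_true(boxContains(f$wholeBox, f$albedoBox))
  }
  expect_error(generatePeelImage(profs[["190"]], size = 32L), ">= 64")
  # no jitter: identical image for identical seed
  set.seed(9); a <- generatePeelImage(profs[["560"]], 64L, jitter = FALSE)
  set.seed(9); b <- generatePeelImage(profs[["560"]], 64L, jitter = FALSE)
  expect_identical(a$image, b$image)
})

test_that("device styling applies gain, offset, blur and noise", {
  img <- array(100, c(64, 64, 3))
  idp <- deviceProfiles()$deviceA
  expect_equal(applyDeviceStyle(img, idp), img)
  bright <- deviceProfile("b", offset = 20)
  expect_equal(applyDeviceStyle(img, bright), array(120, c(64, 64, 3)))
  gain <- deviceProfile("g", gain = c(1.1, 1, 0.9))
  styled <- applyDeviceStyle(img, gain)
  expect_equal(styled[1, 1, 1], 110)
  expect_equal(styled[1, 1, 3], 90)
  noisy <- deviceProfile("n", noiseSigma = 2)
  set.seed(3); n1 <- applyDeviceStyle(img, noisy)
  set.seed(3); n2 <- applyDeviceStyle(img, noisy)
  expect_identical(n1, n2)
  expect_gt(sd(n1), 0)
  expect_true(all(n1 >= 0 & n1 <= 255))
  expect_error(deviceProfile("bad", gain = c(1, 1)), "length 3")
})

test_that("dataset generation conserves counts and pairs devices", {
  counts <- c("190" = 10, "560" = 10, "2800" = 10, "3300" = 10)
  ds <- generateDataset(counts = counts, size = 64L, seed = 5)
  man <- ds$manifest
  expect_identical(nrow(man), 120L)  # 40 specimens x 3 devices
  expect_identical(as.integer(table(man$device)), rep(40L, 3))
  for (cl in names(counts))
    expect_identical(sum(man$label == cl & man$device == "deviceA"), 10L)
  # split 6/2/2 per class, identical across devices for each specimen
  perClass <- table(man$split[man$device == "deviceA"],
                    man$label[man$device == "deviceA"])
  expect_true(all(perClass["train", ] == 6))
  expect_true(all(perClass["val", ] == 2))
  expect_true(all(perClass["test", ] == 2))
  bySpec <- split(man$split, man$id)
  expect_true(all(vapply(bySpec, function(s) length(unique(s)) == 1L, TRUE)))
  # cross-device pairing: ground-truth boxes identical across devices
  byBox <- split(man[, c("wx1", "wy1", "wx2", "wy2", "ax1", "ay1", "ax2",
                         "ay2")], man$id)
  expect_true(all(vapply(byBox, function(b) nrow(unique(b)) == 1L, TRUE)))
  # seeded determinism: bit-identical regeneration
  ds2 <- generateDataset(counts = counts, size = 64L, seed = 5)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$images[[man$key[17]]], ds2$images[[man$key[17]]])
})

test_that("stratified split follows floor-and-distribute rounding", {
  man <- data.frame(id = sprintf("s%03d", 1:399),
                    label = rep(c("190", "560", "2800", "3300"),
                                c(120, 105, 84, 90)))
  sp <- stratifiedSplit(man, seed = 2)
  tab <- table(sp$split, sp$label)
  expect_identical(as.integer(tab["train", c("190", "560", "2800", "3300")]),
                   c(72L, 63L, 50L, 54L))
  expect_identical(as.integer(tab["train", ] + tab["val", ] + tab["test", ]),
                   as.integer(table(man$label)))
  # all-train fractions
  all1 <- stratifiedSplit(man, fractions = c(train = 1, val = 0, test = 0),
                          seed = 1)
  expect_true(all(all1$split == "train"))
  # two seeds: different permutations, identical per-class counts
  spA <- stratifiedSplit(man, seed = 10)
  spB <- stratifiedSplit(man, seed = 11)
  expect_false(identical(spA$split, spB$split))
  expect_identical(table(spA$split, spA$label), table(spB$split, spB$label))
  expect_error(stratifiedSplit(man, fractions = c(train = 0.5, val = 0.2)),
               "sum to 1")
})

test_that("region mean grays separate classes above chance", {
  profs <- classProfiles()
  feats <- NULL; labs <- character()
  set.seed(55)
  for (cl in names(profs)) {
    for (i in 1:12) {
      f <- generatePeelImage(profs[[cl]], size = 64L)
      luma <- toGrayscale(f$image)
      ann <- f$masks$specimen & !f$masks$core
      feats <- rbind(feats, c(mean(luma[ann]), mean(luma[f$masks$core])))
      labs <- c(labs, cl)
    }
  }
  fit <- MASS::lda(feats, grouping = labs)
  acc <- mean(predict(fit)$class == labs)
  expect_gt(acc, 0.4)  # well above the 0.25 chance level
})

test_that("images written to disk round-trip through PNG", {
  dir <- withr::local_tempdir()
  set.seed(77)
  f <- generatePeelImage(classProfiles()[["3300"]], size = 64L)
  p <- writePeelImage(f$image, file.path(dir, "img.png"))
  back <- readPeelImage(p)
  expect_identical(dim(back), dim(f$image))
  expect_lt(max(abs(back - f$image)), 1)  # 8-bit quantization only
  counts <- c("190" = 5, "560" = 5, "2800" = 5, "3300" = 5)
  ds <- generateDataset(counts = counts, size = 64L, seed = 6, dir = dir,
                        devices = deviceProfiles()["deviceA"])
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(ds$manifest$path)))
  expect_null(ds$images)
})
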