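# Desk-scale reference experiments on the synthetic generator, used by the
# test suite and the acceptance script. Problem sizes (25-30 specimens per
# class, 96-128 px renders, 32 px model inputs) are the package's
# desk-scale operating point; the generator's photometric calibration
# (gap d = 40, three device domains) is unchanged from its defaults.

#' Easy synthetic four-class benchmark
#'
#' Generates the default easy synthetic task (large inter-class appearance
#' gaps across pairs, fine-grained albedo cues within pairs), trains the
#' three-branch model and the whole-image-only single-branch baseline on
#' identical data, and reports test accuracies.
#'
#' @param seed RNG seed controlling generation, initialization and
#'   training.
#' @param countsPerClass specimens per class (default 25).
#' @param size render size in pixels (default 128; the whole-image view is
#'   downsampled four-fold to the model input while the albedo crop loses
#'   only half its resolution, preserving the local-cue asymmetry).
#' @param inputSize model input side (default 32).
#' @param epochs maximum training epochs (default 20).
#' @return list with \code{threeBranchAcc} and \code{singleBranchAcc}
#'   (test accuracies in [0, 1]) plus the test-set size \code{nTest}.
#' @export
easySyntheticTask <- function(seed = 1L, countsPerClass = 25L, size = 128L,
                              inputSize = 32L, epochs = 20L) {
  counts <- stats::setNames(rep(countsPerClass, 4),
                            c("190", "560", "2800", "3300"))
  ds <- generateDataset(counts = counts, size = size, seed = seed,
                        devices = deviceProfiles()["deviceA"])
  tr <- prepareSamples(ds, "deviceA", "train", inputSize)
  va <- prepareSamples(ds, "deviceA", "val", inputSize)
  te <- prepareSamples(ds, "deviceA", "test", inputSize)

  m3 <- multiStreamModel(inputSize = inputSize,
                         interaction = interactionConfig(seed = seed),
                         seed = seed)
  m3 <- trainModel(m3, tr, va, epochs = epochs, batchSize = 8L, lr = 2e-3,
                   seed = seed)
  acc3 <- mean(predictClasses(m3, te) == te@labels)

  single <- function(ds) domainDataset(
    lapply(ds@samples, function(s) s["whole"]), ds@labels, ds@deviceId,
    ds@role)
  m1 <- multiStreamModel(branches = "whole", inputSize = inputSize,
                         seed = seed)
  m1 <- trainModel(m1, single(tr), single(va), epochs = epochs,
                   batchSize = 8L, lr = 2e-3, seed = seed)
  acc1 <- mean(predictClasses(m1, single(te)) == te@labels)

  list(threeBranchAcc = acc3, singleBranchAcc = acc1, nTest = length(te))
}

#' Synthetic device-shift benchmark
#'
#' The cross-device protocol at desk scale: train a reduced single-stream
#' model on the neutral source device, evaluate direct transfer on the two
#' shifted target devices, meta-train on the source domain (MAML), then
#' adapt with a 4-way k-shot support set and evaluate on the query
#' remainder, over \code{nRuns} paired support draws per target.
#'
#' @param seed RNG seed.
#' @param countsPerClass specimens per class (default 25).
#' @param size,inputSize render and model-input sizes in pixels.
#' @param epochs source-training epochs.
#' @param config a \linkS4class{MetaConfig}; the default uses 5 inner
#'   steps, 2 tasks per meta-batch and 20 meta-iterations at desk scale.
#' @param nRuns adaptation support draws per target (default 10).
#' @return list with per-target \code{direct} and \code{adapted} accuracy
#'   summaries, the pooled means \code{meanDirect}/\code{meanAdapted}, and
#'   per-target relative improvements in percent.
#' @export
deviceShiftBenchmark <- function(seed = 1L, countsPerClass = 25L,
                                 size = 96L, inputSize = 32L,
                                 epochs = 12L,
                                 config = metaConfig(
                                   innerRate = 0.01, outerRate = 1e-3,
                                   innerSteps = 5L, queryPerClass = 15L,
                                   tasksPerBatch = 2L,
                                   metaIterations = 20L),
                                 nRuns = 10L) {
  counts <- stats::setNames(rep(countsPerClass, 4),
                            c("190", "560", "2800", "3300"))
  ds <- generateDataset(counts = counts, size = size, seed = seed)
  br <- "whole"
  tr <- prepareSamples(ds, "deviceA", "train", inputSize, branches = br)
  va <- prepareSamples(ds, "deviceA", "val", inputSize, branches = br)
  model <- multiStreamModel(branches = br, inputSize = inputSize,
                            seed = seed)
  model <- trainModel(model, tr, va, epochs = epochs, batchSize = 12L,
                      lr = 1e-3, seed = seed)
  src <- prepareSamples(ds, "deviceA", NULL, inputSize, branches = br,
                        role = "source")
  meta <- metaTrain(model, src, config, seed = seed)

  out <- list(direct = list(), adapted = list(),
              relativeImprovement = list())
  directs <- adapteds <- numeric(0)
  for (dv in c("deviceB", "deviceC")) {
    targ <- prepareSamples(ds, dv, NULL, inputSize, branches = br,
                           role = "target")
    direct <- accuracy(directTransferEvaluate(model, targ))
    ad <- adaptAndEvaluate(meta, targ, config, nRuns = nRuns, seed = seed)
    out$direct[[dv]] <- direct
    out$adapted[[dv]] <- ad$summary
    out$relativeImprovement[[dv]] <-
      relativeImprovement(100 * direct, 100 * ad$summary@mean)
    directs <- c(directs, direct)
    adapteds <- c(adapteds, ad$summary@mean)
  }
  out$meanDirect <- mean(directs)
  out$meanAdapted <- mean(adapteds)
  out
}
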