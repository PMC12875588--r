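# Pipeline glue: turning generated/collected images into model-ready
# samples, box CSV serialization, and the YAML-configured end-to-end run.

#' Prepare model-ready samples from a dataset manifest
#'
#' For each manifest row of the requested device/split, the three region
#' crops (whole specimen, exocarp, albedo) are extracted — through the
#' detector + grayscale refinement by default, or from the stored
#' ground-truth boxes — resized to the model input size, and assembled into
#' a \linkS4class{DomainDataset}.
#'
#' @param dataset result of \code{\link{generateDataset}} (manifest plus
#'   in-memory images or on-disk paths).
#' @param device device id to select.
#' @param split split(s) to select (default all).
#' @param inputSize square crop side in pixels.
#' @param branches which crops each sample carries.
#' @param useDetector localize regions with the reference detector and
#'   refine boxes (default); if FALSE, the manifest's ground-truth boxes
#'   are cropped directly.
#' @param params \linkS4class{RefinementParams} for the refinement step.
#' @param role dataset role, "source" or "target".
#' @return a \linkS4class{DomainDataset}.
#' @export
prepareSamples <- function(dataset, device, split = NULL, inputSize = 64L,
                           branches = c("whole", "exocarp", "albedo"),
                           useDetector = TRUE,
                           params = refinementParams(), role = "source") {
  man <- dataset$manifest
  sel <- man$device == device
  if (!is.null(split)) sel <- sel & man$split %in% split
  man <- man[sel, , drop = FALSE]
  if (nrow(man) == 0L) stop("no manifest rows match device/split")
  detector <- contrastDetector()
  samples <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    img <- if (!is.null(dataset$images)) dataset$images[[man$key[i]]]
    else readPeelImage(man$path[i])
    boxes <- list(
      whole = boundingBox(man$wx1[i], man$wy1[i], man$wx2[i], man$wy2[i]),
      exocarp = boundingBox(man$ex1[i], man$ey1[i], man$ex2[i], man$ey2[i]),
      albedo = boundingBox(man$ax1[i], man$ay1[i], man$ax2[i], man$ay2[i]))
    if (useDetector) {
      res <- tryCatch(
        suppressWarnings(localizeAndRefine(img, detector, params)),
        error = function(e) list())
      for (r in res) if (r$kind %in% names(boxes)) boxes[[r$kind]] <- r$box
    }
    samples[[i]] <- lapply(stats::setNames(branches, branches), function(br)
      resizeImage(cropImage(img, boxes[[br]]), inputSize))
  }
  domainDataset(samples, factor(man$label, levels = unique(dataset$manifest$label)),
                deviceId = device, role = role)
}

#' Serialize region detections to CSV
#'
#' Columns: image_id, kind, x1, y1, x2, y2, converged, iterations — one row
#' per refined detection as produced by \code{\link{localizeAndRefine}}.
#'
#' @param results named list: per image id, the list returned by
#'   \code{localizeAndRefine}.
#' @param path output CSV path.
#' @export
writeBoxesCsv <- function(results, path) {
  rows <- list()
  for (id in names(results)) {
    for (r in results[[id]]) {
      b <- boxCoords(r$box)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, kind = r$kind, x1 = b[1], y1 = b[2], x2 = b[3],
        y2 = b[4], converged = r$converged, iterations = r$iterations,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from a YAML configuration
#'
#' Stages: generate the synthetic dataset (optional; a pre-generated
#' directory can be given instead), localize and refine regions, train the
#' classifier on the source device, evaluate on the source test split, and
#' optionally meta-train/adapt across devices. Every stage logs its seed
#' and outputs into the run directory.
#'
#' @param config path to a YAML file or an equivalent named list. Blocks:
#'   \code{data} (counts, size, d, seed), \code{model} (variant, branches,
#'   inputSize, interaction on/off), \code{train} (epochs, batchSize, lr),
#'   \code{meta} (enabled, innerRate, outerRate, innerSteps,
#'   metaIterations, tasksPerBatch, order, nRuns).
#' @param outDir run directory for reports (created if missing); NULL for
#'   no file output.
#' @param dryRun validate the configuration and return it without
#'   executing.
#' @param verbose print stage progress.
#' @return list with the trained model, test metrics, and (when meta is
#'   enabled) per-target direct/adapted accuracies and relative
#'   improvements.
#' @export
runPipeline <- function(config, outDir = NULL, dryRun = FALSE,
                        verbose = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dataCfg <- cfg$data %||% list()
  modelCfg <- cfg$model %||% list()
  trainCfg <- cfg$train %||% list()
  metaCfg <- cfg$meta %||% list()
  seed <- as.integer(dataCfg$seed %||% 1L)
  counts <- unlist(dataCfg$counts %||%
                     c("190" = 30, "560" = 30, "2800" = 30, "3300" = 30))
  if (dryRun) return(invisible(cfg))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  if (verbose) message("generating dataset (seed ", seed, ")")
  ds <- generateDataset(counts = counts,
                        size = as.integer(dataCfg$size %||% 96L),
                        d = dataCfg$d %||% 40, seed = seed)
  inputSize <- as.integer(modelCfg$inputSize %||% 32L)
  branches <- unlist(modelCfg$branches %||%
                       c("whole", "exocarp", "albedo"))
  interaction <- interactionConfig(
    active = isTRUE(modelCfg$interaction %||% TRUE), seed = seed)
  model <- multiStreamModel(branches = branches,
                            variant = modelCfg$variant %||% "reduced",
                            inputSize = inputSize,
                            interaction = interaction,
                            classes = names(counts), seed = seed)
  devices <- unique(ds$manifest$device)
  source <- devices[1]

  if (verbose) message("preparing crops (device ", source, ")")
  trainSet <- prepareSamples(ds, source, "train", inputSize, branches)
  valSet <- prepareSamples(ds, source, "val", inputSize, branches)
  testSet <- prepareSamples(ds, source, "test", inputSize, branches)

  if (verbose) message("training")
  model <- trainModel(model, trainSet, valSet,
                      epochs = as.integer(trainCfg$epochs %||% 20L),
                      batchSize = as.integer(trainCfg$batchSize %||% 16L),
                      lr = trainCfg$lr %||% 1e-3, seed = seed,
                      verbose = verbose)
  metrics <- computeMetrics(predictClasses(model, testSet), testSet@labels)
  out <- list(model = model, metrics = metrics, config = cfg, seed = seed)

  if (isTRUE(metaCfg$enabled)) {
    mc <- metaConfig(
      innerRate = metaCfg$innerRate %||% 0.01,
      outerRate = metaCfg$outerRate %||% 1e-3,
      innerSteps = as.integer(metaCfg$innerSteps %||% 5L),
      nWay = length(counts),
      tasksPerBatch = as.integer(metaCfg$tasksPerBatch %||% 2L),
      metaIterations = as.integer(metaCfg$metaIterations %||% 30L),
      order = metaCfg$order %||% "second")
    if (verbose) message("meta-training on ", source)
    metaSource <- prepareSamples(ds, source, NULL, inputSize, branches,
                                 role = "source")
    metaModel <- metaTrain(model, metaSource, mc, seed = seed)
    cross <- list()
    for (dv in setdiff(devices, source)) {
      targ <- prepareSamples(ds, dv, NULL, inputSize, branches,
                             role = "target")
      direct <- directTransferEvaluate(model, targ)
      adapted <- adaptAndEvaluate(metaModel, targ, mc,
                                  nRuns = as.integer(metaCfg$nRuns %||% 10L),
                                  seed = seed)
      cross[[dv]] <- list(
        direct = accuracy(direct) * 100,
        adapted = adapted$summary@mean * 100,
        adaptedSd = adapted$summary@sd * 100,
        relativeImprovement = relativeImprovement(
          accuracy(direct) * 100, adapted$summary@mean * 100))
    }
    out$metaModel <- metaModel
    out$cross <- cross
  }
  if (!is.null(outDir)) {
    rep <- list(seed = seed,
                accuracy = metrics@accuracy,
                macroRecall = metrics@macroRecall,
                macroF1 = metrics@macroF1,
                cross = out$cross)
    jsonlite::write_json(rep, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(metrics@confusion),
                     file.path(outDir, "confusion.csv"), row.names = FALSE)
    yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
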