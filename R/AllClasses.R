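#' @import methods
NULL

## ---- region localization --------------------------------------------------

#' Axis-aligned bounding box
#'
#' Integer pixel coordinates, 0-based with inclusive corners, following the
#' image-coordinate convention \code{I(x, y)} where \code{x} indexes columns
#' and \code{y} rows. A box must satisfy \code{0 <= x1 < x2 <= W-1} and
#' \code{0 <= y1 < y2 <= H-1} for the image it refers to; a box violating
#' \code{x1 < x2} or \code{y1 < y2} is collapsed and invalid.
#'
#' @slot x1,y1,x2,y2 integer corner coordinates (top-left, bottom-right).
#' @export
setClass("BoundingBox",
         representation(x1 = "integer", y1 = "integer",
                        x2 = "integer", y2 = "integer"),
         validity = function(object) {
           if (length(object@x1) != 1L || length(object@y1) != 1L ||
               length(object@x2) != 1L || length(object@y2) != 1L)
             return("coordinates must be scalars")
           if (anyNA(c(object@x1, object@y1, object@x2, object@y2)))
             return("coordinates must not be NA")
           if (object@x1 < 0L || object@y1 < 0L)
             return("coordinates must be non-negative")
           if (object@x1 >= object@x2 || object@y1 >= object@y2)
             return("collapsed box: need x1 < x2 and y1 < y2")
           TRUE
         })

#' Create a bounding box
#'
#' @param x1,y1,x2,y2 integer corner coordinates, 0-based, corners inclusive.
#' @return A \linkS4class{BoundingBox}.
#' @examples
#' boundingBox(0, 0, 10, 10)
#' @export
boundingBox <- function(x1, y1, x2, y2) {
  new("BoundingBox", x1 = as.integer(x1), y1 = as.integer(y1),
      x2 = as.integer(x2), y2 = as.integer(y2))
}

#' @describeIn boundingBox coordinates as a named integer vector
#' @param box a \linkS4class{BoundingBox}
#' @export
boxCoords <- function(box) {
  c(x1 = box@x1, y1 = box@y1, x2 = box@x2, y2 = box@y2)
}

#' Box area in pixels (inclusive corners)
#' @param box a \linkS4class{BoundingBox}
#' @return integer pixel count
#' @export
boxArea <- function(box) {
  (box@x2 - box@x1 + 1L) * (box@y2 - box@y1 + 1L)
}

#' Is box `inner` contained in box `outer`?
#' @param inner,outer \linkS4class{BoundingBox} objects
#' @export
boxContains <- function(outer, inner) {
  inner@x1 >= outer@x1 && inner@y1 >= outer@y1 &&
    inner@x2 <= outer@x2 && inner@y2 <= outer@y2
}

#' Intersection-over-union of two boxes
#' @param a,b \linkS4class{BoundingBox} objects
#' @return numeric in [0, 1]
#' @export
boxIoU <- function(a, b) {
  ix <- max(0L, min(a@x2, b@x2) - max(a@x1, b@x1) + 1L)
  iy <- max(0L, min(a@y2, b@y2) - max(a@y1, b@y1) + 1L)
  inter <- as.numeric(ix) * iy
  inter / (boxArea(a) + boxArea(b) - inter)
}

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox (x1=%d, y1=%d) -- (x2=%d, y2=%d)  [%d x %d px]\n",
              object@x1, object@y1, object@x2, object@y2,
              object@x2 - object@x1 + 1L, object@y2 - object@y1 + 1L))
})

#' Parameters of grayscale-deviation box refinement
#'
#' @slot step positive integer shrink step in pixels.
#' @slot tau non-negative gray-value deviation threshold.
#' @slot maxIterations iteration guard for the refinement loop.
#' @slot singleUpdatePerCoordinate if TRUE, a coordinate shared by two
#'   violating corners moves by one step per iteration instead of two.
#' @export
setClass("RefinementParams",
         representation(step = "integer", tau = "numeric",
                        maxIterations = "integer",
                        singleUpdatePerCoordinate = "logical"),
         validity = function(object) {
           if (object@step < 1L) return("step must be >= 1")
           if (object@tau < 0) return("tau must be >= 0")
           if (object@maxIterations < 1L) return("maxIterations must be >= 1")
           TRUE
         })

#' Create refinement parameters
#'
#' @param step shrink step in pixels (default 1).
#' @param tau deviation threshold in gray levels (default 20, the operating
#'   value for a specimen/background gray gap of about 40).
#' @param maxIterations loop guard (default 500).
#' @param singleUpdatePerCoordinate conservative shared-coordinate update
#'   (default FALSE: both corner branches may move one coordinate in a single
#'   iteration, as the shrink rules are applied sequentially).
#' @return A \linkS4class{RefinementParams}.
#' @export
refinementParams <- function(step = 1L, tau = 20, maxIterations = 500L,
                             singleUpdatePerCoordinate = FALSE) {
  new("RefinementParams", step = as.integer(step), tau = as.numeric(tau),
      maxIterations = as.integer(maxIterations),
      singleUpdatePerCoordinate = singleUpdatePerCoordinate)
}

#' A detected region of a peel specimen
#'
#' @slot box the detection's \linkS4class{BoundingBox}.
#' @slot kind region label: "whole", "exocarp" or "albedo".
#' @slot confidence detector confidence in [0, 1].
#' @export
setClass("RegionDetection",
         representation(box = "BoundingBox", kind = "character",
                        confidence = "numeric"),
         validity = function(object) {
           if (!object@kind %in% c("whole", "exocarp", "albedo"))
             return("kind must be one of 'whole', 'exocarp', 'albedo'")
           if (object@confidence < 0 || object@confidence > 1)
             return("confidence must lie in [0, 1]")
           TRUE
         })

#' @rdname RegionDetection-class
#' @param box,kind,confidence slots, see class description
#' @export
regionDetection <- function(box, kind, confidence = 1) {
  new("RegionDetection", box = box, kind = kind,
      confidence = as.numeric(confidence))
}

setMethod("show", "RegionDetection", function(object) {
  cat(sprintf("RegionDetection <%s> conf=%.2f ", object@kind,
              object@confidence))
  show(object@box)
})

## ---- synthetic data -------------------------------------------------------

#' Appearance profile of one vintage class
#'
#' Controls the rendered look of synthetic peel specimens of one class.
#' Gray levels are chosen relative to the background so the specimen-vs-
#' background luma gap stays near the configured contrast; classes are
#' separated mainly by hue, texture amplitude/frequency and fiber density,
#' with small (within-gap-tolerance) gray offsets.
#'
#' @slot label class label, one of "190", "560", "2800", "3300".
#' @slot exocarpOffset,albedoOffset luma offsets (gray levels) of the outer
#'   annulus and inner core relative to the nominal specimen gray.
#' @slot texAmp,texFreq sinusoidal exocarp texture amplitude (gray levels)
#'   and frequency (cycles across the image).
#' @slot fiberDensity expected number of albedo fiber streaks.
#' @slot hue per-channel chroma coefficients (length 3, approx. zero-luma).
#' @export
setClass("ClassProfile",
         representation(label = "character", exocarpOffset = "numeric",
                        albedoOffset = "numeric", texAmp = "numeric",
                        texFreq = "numeric", fiberDensity = "numeric",
                        hue = "numeric"),
         validity = function(object) {
           if (length(object@hue) != 3L) return("hue must have length 3")
           if (object@texAmp < 0) return("texAmp must be >= 0")
           TRUE
         })

#' @rdname ClassProfile-class
#' @param label,exocarpOffset,albedoOffset,texAmp,texFreq,fiberDensity,hue
#'   slots, see class description
#' @export
classProfile <- function(label, exocarpOffset = 0, albedoOffset = 0,
                         texAmp = 4, texFreq = 6, fiberDensity = 12,
                         hue = c(0, 0, 0)) {
  new("ClassProfile", label = as.character(label),
      exocarpOffset = exocarpOffset, albedoOffset = albedoOffset,
      texAmp = texAmp, texFreq = texFreq, fiberDensity = fiberDensity,
      hue = hue)
}

#' Photometric profile of a capture device
#'
#' Emulates device-induced domain shift: per-channel color gain, global
#' brightness offset, gaussian blur (sharpness) and sensor noise. The
#' identity profile (unit gains, zero offset/blur/noise) leaves images
#' unchanged up to clamping.
#'
#' @slot id device identifier.
#' @slot gain per-channel multiplicative gain (length 3).
#' @slot offset additive brightness offset in gray levels.
#' @slot blurSigma gaussian blur standard deviation in pixels (0 = none).
#' @slot noiseSigma additive gaussian noise standard deviation (0 = none).
#' @export
setClass("DeviceProfile",
         representation(id = "character", gain = "numeric",
                        offset = "numeric", blurSigma = "numeric",
                        noiseSigma = "numeric"),
         validity = function(object) {
           if (length(object@gain) != 3L) return("gain must have length 3")
           if (any(object@gain <= 0)) return("gains must be positive")
           if (object@blurSigma < 0 || object@noiseSigma < 0)
             return("blurSigma and noiseSigma must be >= 0")
           TRUE
         })

#' @rdname DeviceProfile-class
#' @param id,gain,offset,blurSigma,noiseSigma slots, see class description
#' @export
deviceProfile <- function(id, gain = c(1, 1, 1), offset = 0,
                          blurSigma = 0, noiseSigma = 0) {
  new("DeviceProfile", id = as.character(id), gain = gain,
      offset = offset, blurSigma = blurSigma, noiseSigma = noiseSigma)
}

setMethod("show", "DeviceProfile", function(object) {
  cat(sprintf("DeviceProfile '%s': gain=(%.2f, %.2f, %.2f) offset=%+.1f blur=%.1f noise=%.1f\n",
              object@id, object@gain[1], object@gain[2], object@gain[3],
              object@offset, object@blurSigma, object@noiseSigma))
})

## ---- model configuration --------------------------------------------------

#' Channel-level feature interaction configuration
#'
#' @slot forwardRatio fraction of full-branch channels injected into each
#'   local branch (default 0.10).
#' @slot reverseRatio fraction of each local branch's channels injected back
#'   into the full branch (default 0.05).
#' @slot stage residual stage (1--4) after which interaction is applied
#'   (default 2).
#' @slot seed RNG seed used for deterministic index draws at evaluation.
#' @slot active master switch.
#' @slot freezeIndices if TRUE, index sets are drawn once from `seed` and
#'   reused for the whole run instead of being resampled per training step.
#' @slot reverseUsesOriginal if TRUE the reverse phase injects the
#'   pre-interaction local maps (the literal update equations) rather than
#'   the forward-updated ones.
#' @export
setClass("InteractionConfig",
         representation(forwardRatio = "numeric", reverseRatio = "numeric",
                        stage = "integer", seed = "integer",
                        active = "logical", freezeIndices = "logical",
                        reverseUsesOriginal = "logical"),
         validity = function(object) {
           if (object@forwardRatio < 0 || object@forwardRatio > 1 ||
               object@reverseRatio < 0 || object@reverseRatio > 1)
             return("ratios must lie in [0, 1]")
           if (!object@stage %in% 1:4) return("stage must be in 1..4")
           TRUE
         })

#' @rdname InteractionConfig-class
#' @param forwardRatio,reverseRatio,stage,seed,active,freezeIndices,reverseUsesOriginal
#'   slots, see class description
#' @export
interactionConfig <- function(forwardRatio = 0.10, reverseRatio = 0.05,
                              stage = 2L, seed = 1L, active = TRUE,
                              freezeIndices = FALSE,
                              reverseUsesOriginal = FALSE) {
  new("InteractionConfig", forwardRatio = forwardRatio,
      reverseRatio = reverseRatio, stage = as.integer(stage),
      seed = as.integer(seed), active = active,
      freezeIndices = freezeIndices,
      reverseUsesOriginal = reverseUsesOriginal)
}

#' Fusion-head configuration
#'
#' @slot compressDim channels after the per-branch 1x1 compression.
#' @slot nClasses number of output classes.
#' @slot auxWeight weight of each branch's auxiliary classification loss.
#' @export
setClass("FusionConfig",
         representation(compressDim = "integer", nClasses = "integer",
                        auxWeight = "numeric"),
         validity = function(object) {
           if (object@compressDim < 1L) return("compressDim must be >= 1")
           if (object@nClasses < 2L) return("nClasses must be >= 2")
           TRUE
         })

#' @rdname FusionConfig-class
#' @param compressDim,nClasses,auxWeight slots, see class description
#' @export
fusionConfig <- function(compressDim = 512L, nClasses = 4L, auxWeight = 1) {
  new("FusionConfig", compressDim = as.integer(compressDim),
      nClasses = as.integer(nClasses), auxWeight = as.numeric(auxWeight))
}

## ---- meta learning ---------------------------------------------------------

#' MAML meta-learning configuration
#'
#' @slot innerRate inner-loop (adaptation) gradient-descent rate alpha.
#' @slot outerRate outer-loop meta rate beta.
#' @slot innerSteps number of inner gradient steps K (default 5).
#' @slot nWay,kShot episodic task shape (default 4-way, 5-shot).
#' @slot queryPerClass query samples per class in each task (default 15).
#' @slot tasksPerBatch tasks aggregated per meta-update.
#' @slot metaIterations number of meta-updates.
#' @slot order "second" (exact two-level gradient) or "first"
#'   (first-order approximation).
#' @slot adaptHeadOnly restrict inner-loop adaptation to classifier heads.
#' @export
setClass("MetaConfig",
         representation(innerRate = "numeric", outerRate = "numeric",
                        innerSteps = "integer", nWay = "integer",
                        kShot = "integer", queryPerClass = "integer",
                        tasksPerBatch = "integer", metaIterations = "integer",
                        order = "character", adaptHeadOnly = "logical"),
         validity = function(object) {
           if (object@innerRate <= 0 || object@outerRate <= 0)
             return("learning rates must be positive")
           if (object@innerSteps < 1L) return("innerSteps must be >= 1")
           if (!object@order %in% c("second", "first"))
             return("order must be 'second' or 'first'")
           TRUE
         })

#' @rdname MetaConfig-class
#' @param innerRate,outerRate,innerSteps,nWay,kShot,queryPerClass,tasksPerBatch,metaIterations,order,adaptHeadOnly
#'   slots, see class description
#' @export
metaConfig <- function(innerRate = 0.01, outerRate = 1e-3, innerSteps = 5L,
                       nWay = 4L, kShot = 5L, queryPerClass = 15L,
                       tasksPerBatch = 4L, metaIterations = 100L,
                       order = "second", adaptHeadOnly = FALSE) {
  new("MetaConfig", innerRate = innerRate, outerRate = outerRate,
      innerSteps = as.integer(innerSteps), nWay = as.integer(nWay),
      kShot = as.integer(kShot), queryPerClass = as.integer(queryPerClass),
      tasksPerBatch = as.integer(tasksPerBatch),
      metaIterations = as.integer(metaIterations), order = order,
      adaptHeadOnly = adaptHeadOnly)
}

#' Labeled samples from one capture-device domain
#'
#' @slot samples list of model-ready samples (each a named list of branch
#'   crops, see \code{\link{prepareSamples}}).
#' @slot labels factor of class labels, one per sample.
#' @slot deviceId capture device identifier.
#' @slot role "source" (meta-training) or "target" (meta-testing).
#' @export
setClass("DomainDataset",
         representation(samples = "list", labels = "factor",
                        deviceId = "character", role = "character"),
         validity = function(object) {
           if (length(object@samples) != length(object@labels))
             return("samples and labels lengths differ")
           if (!object@role %in% c("source", "target"))
             return("role must be 'source' or 'target'")
           TRUE
         })

#' @rdname DomainDataset-class
#' @param samples,labels,deviceId,role slots, see class description
#' @export
domainDataset <- function(samples, labels, deviceId, role = "source") {
  new("DomainDataset", samples = samples, labels = as.factor(labels),
      deviceId = as.character(deviceId), role = role)
}

setMethod("show", "DomainDataset", function(object) {
  cat(sprintf("DomainDataset '%s' (%s): %d samples, %d classes\n",
              object@deviceId, object@role, length(object@samples),
              nlevels(object@labels)))
  print(table(object@labels))
})

#' @describeIn DomainDataset-class number of samples
#' @param x a \code{DomainDataset}
#' @export
setMethod("length", "DomainDataset", function(x) length(x@samples))

## ---- evaluation ------------------------------------------------------------

#' Classification metrics report
#'
#' @slot accuracy overall fraction of correct predictions.
#' @slot macroRecall,macroF1 macro-averaged recall and F1 (equal class
#'   weights).
#' @slot perClassAccuracy named per-class recall (diagonal over row sums).
#' @slot confusion C x C count matrix; rows = true class, cols = predicted.
#' @export
setClass("MetricsReport",
         representation(accuracy = "numeric", macroRecall = "numeric",
                        macroF1 = "numeric", perClassAccuracy = "numeric",
                        confusion = "matrix"),
         validity = function(object) {
           if (object@accuracy < 0 || object@accuracy > 1)
             return("accuracy must lie in [0, 1]")
           TRUE
         })

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy %.4f | macro recall %.4f | macro F1 %.4f\n",
              object@accuracy, object@macroRecall, object@macroF1))
  cat("Confusion matrix (rows = truth):\n")
  print(object@confusion)
})

#' Summary of repeated seeded runs
#'
#' @slot values per-seed metric values.
#' @slot mean,sd mean and sample standard deviation (n-1 denominator).
#' @slot seeds seeds used, one per run.
#' @export
setClass("RunSummary",
         representation(values = "numeric", mean = "numeric", sd = "numeric",
                        seeds = "integer"),
         validity = function(object) {
           if (length(object@values) >= 1 &&
               (object@mean < min(object@values) - 1e-12 ||
                object@mean > max(object@values) + 1e-12))
             return("mean must lie within the range of values")
           TRUE
         })

setMethod("show", "RunSummary", function(object) {
  cat(sprintf("RunSummary over %d runs: mean %.4f, sd %.4f\n",
              length(object@values), object@mean, object@sd))
})
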