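# Region localization: grayscale statistics, corner-deviation box
# refinement, and a contrast-based reference detector.
#
# Images use gray values in [0, 255]; a color image is an (H, W, 3) array, a
# gray image an (H, W) matrix. Pixel access follows the I(x, y) convention
# with x the 0-based column and y the 0-based row.

#' Convert a color image to grayscale
#'
#' Luma-weighted combination with the usual 0.299/0.587/0.114 weights,
#' clamped to [0, 255].
#'
#' @param image (H, W, 3) array with channel values in [0, 255].
#' @return (H, W) numeric matrix of gray values.
#' @examples
#' img <- array(100, c(4, 4, 3))
#' toGrayscale(img)[1, 1]  # 100
#' @export
toGrayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("toGrayscale() expects an (H, W, 3) color image")
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  dim(g) <- d[1:2]
  g[g < 0] <- 0
  g[g > 255] <- 255
  g
}

#' Global grayscale mean of an image
#'
#' @param gray (H, W) matrix of gray values in [0, 255].
#' @return scalar mean gray value.
#' @export
globalMean <- function(gray) {
  if (length(gray) == 0L) stop("empty image")
  mean(gray)
}

# 0-based pixel lookup honoring I(x, y): column x, row y.
grayAt <- function(gray, x, y) gray[y + 1L, x + 1L]

#' Corner gray-value deviations of a bounding box
#'
#' Extracts the gray values at the four box corners (TL, TR, BL, BR) and
#' returns their absolute deviations from the global mean \code{mu}.
#'
#' @param gray (H, W) gray image.
#' @param box a \linkS4class{BoundingBox} inside the image.
#' @param mu global gray mean (defaults to \code{globalMean(gray)}).
#' @return named numeric vector with elements TL, TR, BL, BR; all >= 0.
#' @export
cornerDeviations <- function(gray, box, mu = globalMean(gray)) {
  H <- nrow(gray); W <- ncol(gray)
  if (box@x2 > W - 1L || box@y2 > H - 1L)
    stop("box exceeds image bounds")
  c(TL = abs(grayAt(gray, box@x1, box@y1) - mu),
    TR = abs(grayAt(gray, box@x2, box@y1) - mu),
    BL = abs(grayAt(gray, box@x1, box@y2) - mu),
    BR = abs(grayAt(gray, box@x2, box@y2) - mu))
}

#' Deviation threshold from specimen and background gray means
#'
#' The threshold is half the gray-level difference between the specimen and
#' the background, \code{tau = |muCrp - muBg| / 2}; a gap of about 40 gray
#' levels gives the operating value tau = 20. Symmetric in its arguments.
#'
#' @param muCrp mean gray value of the specimen region.
#' @param muBg mean gray value of the background.
#' @return the threshold tau (non-negative).
#' @examples
#' computeThreshold(200, 160)  # 20
#' @export
computeThreshold <- function(muCrp, muBg) {
  stopifnot(muCrp >= 0, muCrp <= 255, muBg >= 0, muBg <= 255)
  abs(muCrp - muBg) / 2
}

#' Grayscale-deviation bounding-box refinement
#'
#' Iteratively shrinks a box inward: per iteration the gray values at the
#' four corners are compared against the global image mean, and each corner
#' whose absolute deviation exceeds \code{tau} pulls its two coordinates
#' inward by the shrink step (TL: x1+s, y1+s; TR: x2-s, y1+s; BL: x1+s,
#' y2-s; BR: x2-s, y2-s). The four corner rules are applied sequentially
#' within one iteration, so a coordinate shared by two violating corners
#' moves by two steps unless \code{singleUpdatePerCoordinate} is set. The
#' loop terminates when all four deviations are at or below \code{tau}
#' (converged), or when the box would collapse or \code{maxIterations} is
#' exhausted (not converged; the last valid box is returned).
#'
#' @param gray (H, W) gray image.
#' @param box starting \linkS4class{BoundingBox}.
#' @param params a \linkS4class{RefinementParams}.
#' @param mu global mean override (defaults to the whole-image mean).
#' @return list with elements \code{box} (refined \linkS4class{BoundingBox},
#'   always contained in the input box), \code{iterations} (shrink
#'   iterations used) and \code{converged} (logical).
#' @export
refineBox <- function(gray, box, params = refinementParams(),
                      mu = globalMean(gray)) {
  H <- nrow(gray); W <- ncol(gray)
  if (box@x2 > W - 1L || box@y2 > H - 1L)
    stop("box exceeds image bounds")
  s <- params@step
  tau <- params@tau
  x1 <- box@x1; y1 <- box@y1; x2 <- box@x2; y2 <- box@y2
  iter <- 0L
  repeat {
    dev <- c(abs(grayAt(gray, x1, y1) - mu), abs(grayAt(gray, x2, y1) - mu),
             abs(grayAt(gray, x1, y2) - mu), abs(grayAt(gray, x2, y2) - mu))
    if (all(dev <= tau)) {
      return(list(box = boundingBox(x1, y1, x2, y2), iterations = iter,
                  converged = TRUE))
    }
    if (iter >= params@maxIterations) {
      return(list(box = boundingBox(x1, y1, x2, y2), iterations = iter,
                  converged = FALSE))
    }
    nx1 <- x1; ny1 <- y1; nx2 <- x2; ny2 <- y2
    if (params@singleUpdatePerCoordinate) {
      if (dev[1] > tau) { nx1 <- x1 + s; ny1 <- y1 + s }
      if (dev[2] > tau) { nx2 <- x2 - s; ny1 <- y1 + s }
      if (dev[3] > tau) { nx1 <- x1 + s; ny2 <- y2 - s }
      if (dev[4] > tau) { nx2 <- x2 - s; ny2 <- y2 - s }
    } else {
      if (dev[1] > tau) { nx1 <- nx1 + s; ny1 <- ny1 + s }
      if (dev[2] > tau) { nx2 <- nx2 - s; ny1 <- ny1 + s }
      if (dev[3] > tau) { nx1 <- nx1 + s; ny2 <- ny2 - s }
      if (dev[4] > tau) { nx2 <- nx2 - s; ny2 <- ny2 - s }
    }
    if (nx1 >= nx2 || ny1 >= ny2) {
      # next shrink would collapse the box: stop at the last valid box
      return(list(box = boundingBox(x1, y1, x2, y2), iterations = iter,
                  converged = FALSE))
    }
    x1 <- nx1; y1 <- ny1; x2 <- nx2; y2 <- ny2
    iter <- iter + 1L
  }
}

## ---- reference detector ---------------------------------------------------

#' Contrast-based reference region detector
#'
#' Returns a detector closure implementing the pluggable detection contract
#' \code{propose(image) -> list of RegionDetection}. Any detector honoring
#' that contract (e.g. an external trained detector) can be substituted in
#' \code{\link{detectRegions}}; this reference implementation needs no
#' pretrained weights. It thresholds the gray image at the midpoint between
#' the background and specimen means (estimated by two-class mean iteration),
#' labels connected components, and for each sufficiently large component
#' emits a whole-specimen box, an exocarp box (bounds of the outer annulus)
#' and an albedo box (bounds of the inner core, taken as the component's
#' central ellipse scaled by \code{coreScale}).
#'
#' @param minArea minimum component area in pixels to report.
#' @param coreScale linear scale of the inner (albedo) core relative to the
#'   fitted specimen ellipse (default 0.55, matching the synthetic
#'   generator's construction).
#' @return function(image) returning a list of
#'   \linkS4class{RegionDetection}.
#' @export
contrastDetector <- function(minArea = 200, coreScale = 0.55) {
  function(image) {
    gray <- if (length(dim(image)) == 3L) toGrayscale(image) else image
    thr <- midpointThreshold(gray)
    fg <- gray < thr  # specimens are darker than the background
    if (!any(fg)) return(list())
    lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
    lab <- as.matrix(EBImage::imageData(lab))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= minArea)
    if (length(keep) == 0L) return(list())
    total <- nrow(gray) * ncol(gray)
    out <- list()
    for (comp in keep) {
      mask <- lab == comp
      idx <- which(mask, arr.ind = TRUE)  # (row, col) 1-based
      ys <- idx[, 1] - 1L; xs <- idx[, 2] - 1L
      whole <- boundingBox(min(xs), min(ys), max(xs), max(ys))
      conf <- min(1, sizes[comp] / (0.25 * total))
      # fit the specimen ellipse by second moments; the core is a scaled copy
      cx <- mean(xs); cy <- mean(ys)
      rx <- 2 * stats::sd(xs); ry <- 2 * stats::sd(ys)
      core <- ((xs - cx) / (coreScale * rx))^2 +
        ((ys - cy) / (coreScale * ry))^2 <= 1
      out[[length(out) + 1L]] <- regionDetection(whole, "whole", conf)
      out[[length(out) + 1L]] <- regionDetection(whole, "exocarp", conf)
      if (sum(core) >= 4L) {
        ab <- boundingBox(min(xs[core]), min(ys[core]),
                          max(xs[core]), max(ys[core]))
        out[[length(out) + 1L]] <- regionDetection(ab, "albedo", conf)
      }
    }
    out
  }
}

# Ridler-Calvard style two-class mean iteration; converges to the midpoint
# between the background and specimen gray means.
midpointThreshold <- function(gray, tol = 0.5, maxIter = 50L) {
  thr <- mean(gray)
  for (i in seq_len(maxIter)) {
    lo <- gray[gray < thr]; hi <- gray[gray >= thr]
    if (length(lo) == 0L || length(hi) == 0L) break
    newThr <- (mean(lo) + mean(hi)) / 2
    if (abs(newThr - thr) < tol) return(newThr)
    thr <- newThr
  }
  thr
}

#' Detect specimen regions with a pluggable detector
#'
#' @param image (H, W, 3) color image.
#' @param detector a detector closure; defaults to
#'   \code{\link{contrastDetector}()}.
#' @return list of \linkS4class{RegionDetection}; empty (with a message via
#'   \code{warning}) when nothing is detected.
#' @export
detectRegions <- function(image, detector = contrastDetector()) {
  dets <- detector(image)
  dets <- Filter(function(d) isTRUE(validObject(d@box, test = TRUE)), dets)
  if (length(dets) == 0L)
    warning("no regions detected", call. = FALSE)
  dets
}

#' Localize exocarp/albedo regions and refine their boxes
#'
#' Composition of \code{\link{detectRegions}} and \code{\link{refineBox}}:
#' every detected box is tightened with the grayscale corner-deviation rule,
#' and crops of the refined boxes are returned alongside.
#'
#' @param image (H, W, 3) color image.
#' @param detector detector closure (default \code{contrastDetector()}).
#' @param params \linkS4class{RefinementParams}.
#' @return list of results, one per detection, each with elements
#'   \code{kind}, \code{detected} (original box), \code{box} (refined),
#'   \code{iterations}, \code{converged} and \code{crop} (color sub-image).
#' @export
localizeAndRefine <- function(image, detector = contrastDetector(),
                              params = refinementParams()) {
  gray <- toGrayscale(image)
  mu <- globalMean(gray)
  dets <- detectRegions(image, detector)
  lapply(dets, function(d) {
    r <- refineBox(gray, d@box, params, mu = mu)
    list(kind = d@kind, detected = d@box, box = r$box,
         iterations = r$iterations, converged = r$converged,
         crop = cropImage(image, r$box))
  })
}

#' Crop a color image to a bounding box
#' @param image (H, W, 3) array.
#' @param box a \linkS4class{BoundingBox} (0-based, corners inclusive).
#' @return the (h, w, 3) sub-array.
#' @export
cropImage <- function(image, box) {
  image[(box@y1 + 1L):(box@y2 + 1L), (box@x1 + 1L):(box@x2 + 1L), ,
        drop = FALSE]
}
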