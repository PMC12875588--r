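# Synthetic peel-image generator: elliptical specimens (textured exocarp
# annulus, fibrous albedo core) on a uniform light background, four vintage
# classes, device-style photometric domains, and manifests with ground-truth
# geometry.
#
# The generator is calibrated around one contrast statistic: the luma gap
# between the specimen and the background is approximately d (default 40
# gray levels), the operating regime in which the refinement threshold
# tau = d/2 = 20 separates specimen from background corners. Classes are
# separated by hue, texture amplitude/frequency, fiber density and small
# (within-gap-tolerance) region-gray offsets.

BG_GRAY <- 225

# Zero-luma chroma vector: pick red/blue coefficients, solve green so that
# 0.299 r + 0.587 g + 0.114 b = 0 and hue shifts leave the gray image (and
# hence the refinement statistics) unchanged.
chroma <- function(r, b) c(r, -(0.299 * r + 0.114 * b) / 0.587, b)

#' Default appearance profiles of the four vintage classes
#'
#' Labels follow the four price categories (CNY/kg). The two
#' counterfeit/younger classes render brighter orange, the two aged classes
#' darker brown — a coarse (whole-image) cue separating the pairs. Within
#' each pair, classes differ in fine-grained local structure only: albedo
#' fiber density and exocarp texture frequency, the kind of cue that
#' motivates zoomed region branches over a single whole-image view.
#' Exocarp/albedo gray offsets are balanced in proportion to the annulus
#' and core areas (core area fraction 0.55^2), so each specimen's overall
#' luma equals the nominal specimen gray and the realized
#' specimen-background gap stays at the configured contrast; the albedo
#' core is re-centered after fiber rendering so within-pair region means
#' coincide.
#'
#' @return named list of \linkS4class{ClassProfile} objects.
#' @export
classProfiles <- function() {
  list(
    "190"  = classProfile("190",  exocarpOffset = -3, albedoOffset = 6.9,
                          texAmp = 4, texFreq = 5, fiberDensity = 3,
                          hue = chroma(0.15, -0.15)),
    "560"  = classProfile("560",  exocarpOffset = -3, albedoOffset = 6.9,
                          texAmp = 4, texFreq = 5, fiberDensity = 18,
                          hue = chroma(0.15, -0.15)),
    "2800" = classProfile("2800", exocarpOffset = 3, albedoOffset = -6.9,
                          texAmp = 4, texFreq = 7, fiberDensity = 3,
                          hue = chroma(-0.12, 0.12)),
    "3300" = classProfile("3300", exocarpOffset = 3, albedoOffset = -6.9,
                          texAmp = 4, texFreq = 7, fiberDensity = 18,
                          hue = chroma(-0.12, 0.12)))
}

#' Default capture-device photometric profiles
#'
#' Three device-style domains: a neutral reference device (identity
#' profile) and two shifted domains differing in color balance, brightness
#' and sharpness, emulating consumer-phone processing differences.
#'
#' @return named list of \linkS4class{DeviceProfile} objects.
#' @export
deviceProfiles <- function() {
  list(
    deviceA = deviceProfile("deviceA"),
    deviceB = deviceProfile("deviceB", gain = c(1.08, 0.97, 0.90),
                            offset = 18, blurSigma = 1.5, noiseSigma = 3),
    deviceC = deviceProfile("deviceC", gain = c(0.90, 0.97, 1.10),
                            offset = -22, blurSigma = 1.0, noiseSigma = 3))
}

#' Render one synthetic peel specimen
#'
#' A uniform light background holds one elliptical specimen: the outer
#' annulus carries the exocarp texture, the inner core (ellipse scaled by
#' \code{coreScale}) the albedo rendering with fiber streaks. Ground-truth
#' boxes are the tight axis-aligned bounds of each region mask. Geometry
#' and texture are drawn from R's current RNG stream.
#'
#' @param profile a \linkS4class{ClassProfile}.
#' @param size square image side in pixels (>= 64).
#' @param d configured specimen-background luma gap (default 40).
#' @param jitter logical; randomize center/radii slightly (default TRUE).
#' @param coreScale linear scale of the albedo core (default 0.55).
#' @return list with \code{image} ((size, size, 3), values 0--255),
#'   \code{wholeBox}, \code{exocarpBox}, \code{albedoBox}
#'   (\linkS4class{BoundingBox}es), \code{masks} (specimen/core logicals)
#'   and \code{gap} (realized specimen-background luma gap, within d +- 5).
#' @export
generatePeelImage <- function(profile, size = 128L, d = 40,
                              jitter = TRUE, coreScale = 0.55) {
  if (size < 64L) stop("size must be >= 64")
  S <- as.integer(size)
  # The specimen fills ~65% of the canvas so the global mean sits between
  # the specimen and background grays: background corners then deviate by
  # ~f*d > tau (shrinking engages) and interior corners by ~(1-f)*d < tau
  # (shrinking stops), the regime the tau = d/2 rule is built for.
  cx <- S / 2; cy <- S / 2
  rx <- 0.455 * S; ry <- 0.455 * S
  if (jitter) {
    cx <- cx + stats::runif(1, -0.008, 0.008) * S
    cy <- cy + stats::runif(1, -0.008, 0.008) * S
    rx <- rx * stats::runif(1, 0.985, 1.015)
    ry <- ry * stats::runif(1, 0.985, 1.015)
    # keep jitter extremes on the canvas at the smallest supported sizes
    rx <- min(rx, cx - 1, S - 2 - cx)
    ry <- min(ry, cy - 1, S - 2 - cy)
  }
  if (cx - rx < 1 || cx + rx > S - 2 || cy - ry < 1 || cy + ry > S - 2)
    stop("degenerate geometry: specimen ellipse exceeds the canvas")
  # pixel-center coordinates, 0-based
  xs <- matrix(rep(0:(S - 1L), each = S), S, S)   # column index
  ys <- matrix(rep(0:(S - 1L), times = S), S, S)  # row index
  e <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2
  specimen <- e <= 1
  core <- ((xs - cx) / (coreScale * rx))^2 +
    ((ys - cy) / (coreScale * ry))^2 <= 1
  annulus <- specimen & !core

  base <- BG_GRAY - d
  luma <- matrix(BG_GRAY, S, S)
  tex <- profile@texAmp *
    sin(2 * pi * profile@texFreq * xs / S + stats::runif(1, 0, 2 * pi)) *
    sin(2 * pi * profile@texFreq * ys / S + stats::runif(1, 0, 2 * pi))
  luma[annulus] <- base + profile@exocarpOffset + tex[annulus] +
    stats::rnorm(sum(annulus))
  luma[core] <- base + profile@albedoOffset +
    stats::rnorm(sum(core), sd = 1.5)
  # albedo fiber streaks: thin radial brightenings inside the core; the
  # core is re-centered afterwards so fiber density changes texture, not
  # the region's mean gray
  nFib <- stats::rpois(1, profile@fiberDensity)
  if (nFib > 0) {
    for (i in seq_len(nFib)) {
      phi <- stats::runif(1, 0, 2 * pi)
      rmax <- coreScale * min(rx, ry) * stats::runif(1, 0.5, 0.95)
      t <- seq(0.1, 1, by = 1 / rmax)
      px <- round(cx + t * rmax * cos(phi))
      py <- round(cy + t * rmax * sin(phi))
      ok <- px >= 0 & px < S & py >= 0 & py < S
      luma[cbind(py[ok] + 1L, px[ok] + 1L)] <-
        luma[cbind(py[ok] + 1L, px[ok] + 1L)] + 7
    }
  }
  luma[core] <- luma[core] - mean(luma[core]) +
    (base + profile@albedoOffset)
  img <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    plane <- luma
    plane[specimen] <- plane[specimen] * (1 + profile@hue[ch])
    img[, , ch] <- plane
  }
  img[img < 0] <- 0; img[img > 255] <- 255

  gap <- abs(mean(luma[specimen]) - mean(luma[!specimen]))
  maskBox <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    boundingBox(min(idx[, 2]) - 1L, min(idx[, 1]) - 1L,
                max(idx[, 2]) - 1L, max(idx[, 1]) - 1L)
  }
  list(image = img,
       wholeBox = maskBox(specimen),
       exocarpBox = maskBox(annulus),
       albedoBox = maskBox(core),
       masks = list(specimen = specimen, core = core),
       gap = gap)
}

#' Apply a device's photometric style to an image
#'
#' Per-channel gain, then brightness offset, then gaussian blur, then
#' additive gaussian noise; the result is clamped to [0, 255]. The identity
#' profile returns the input unchanged (up to clamping).
#'
#' @param image (H, W, 3) array, values 0--255.
#' @param device a \linkS4class{DeviceProfile}.
#' @return styled (H, W, 3) array.
#' @export
applyDeviceStyle <- function(image, device) {
  out <- image
  for (ch in 1:3) out[, , ch] <- out[, , ch] * device@gain[ch]
  out <- out + device@offset
  if (device@blurSigma > 0) {
    e <- EBImage::Image(aperm(out, c(2, 1, 3)) / 255, colormode = "Color")
    e <- EBImage::gblur(e, sigma = device@blurSigma)
    out <- aperm(as.array(e), c(2, 1, 3)) * 255
  }
  if (device@noiseSigma > 0)
    out <- out + stats::rnorm(length(out), sd = device@noiseSigma)
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

#' Generate a synthetic peel dataset across devices
#'
#' Renders one base specimen per (class, index) and re-renders the same
#' geometry under each device profile, emulating a design where the same
#' physical specimens are photographed by every device. Ground-truth boxes
#' are therefore identical across devices for a given specimen. A
#' stratified 60/20/20 train/val/test split is assigned per specimen (so a
#' specimen keeps its split in every device domain).
#'
#' @param counts named per-class specimen counts; the default
#'   \code{c("190" = 120, "560" = 105, "2800" = 84, "3300" = 90)} gives the
#'   399-specimen reference configuration.
#' @param devices list of \linkS4class{DeviceProfile}s (default
#'   \code{deviceProfiles()}).
#' @param d specimen-background luma gap (default 40).
#' @param size image side in pixels.
#' @param seed RNG seed; regeneration from (configuration, seed) is
#'   bit-identical.
#' @param dir output directory for PNG images; when NULL images are kept
#'   in memory in the returned \code{images} list.
#' @param fractions split fractions (must sum to 1).
#' @return list with \code{manifest} (data.frame: id, path, label, device,
#'   split, ground-truth box columns wx1..ay2, gap) and \code{images}
#'   (named list of arrays when \code{dir} is NULL).
#' @export
generateDataset <- function(counts = c("190" = 120, "560" = 105,
                                       "2800" = 84, "3300" = 90),
                            devices = deviceProfiles(), d = 40,
                            size = 128L, seed = 1L, dir = NULL,
                            fractions = c(train = 0.6, val = 0.2,
                                          test = 0.2)) {
  stopifnot(all(counts >= 5), length(devices) >= 1)
  profiles <- classProfiles()[names(counts)]
  if (anyNA(names(profiles))) stop("unknown class label in counts")
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  rows <- list()
  images <- list()
  withSeed(seed, {
    for (cl in names(counts)) {
      for (i in seq_len(counts[[cl]])) {
        spec <- generatePeelImage(profiles[[cl]], size = size, d = d)
        id <- sprintf("%s_%03d", cl, i)
        for (dv in devices) {
          styled <- applyDeviceStyle(spec$image, dv)
          key <- sprintf("%s_%s", id, dv@id)
          path <- if (is.null(dir)) NA_character_
          else file.path(dir, paste0(key, ".png"))
          if (!is.null(dir)) writePeelImage(styled, path)
          else images[[key]] <- styled
          w <- boxCoords(spec$wholeBox); e <- boxCoords(spec$exocarpBox)
          a <- boxCoords(spec$albedoBox)
          rows[[length(rows) + 1L]] <- data.frame(
            id = id, key = key, path = path, label = cl, device = dv@id,
            split = NA_character_,
            wx1 = w[1], wy1 = w[2], wx2 = w[3], wy2 = w[4],
            ex1 = e[1], ey1 = e[2], ex2 = e[3], ey2 = e[4],
            ax1 = a[1], ay1 = a[2], ax2 = a[3], ay2 = a[4],
            gap = spec$gap, stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  manifest <- stratifiedSplit(manifest, fractions, seed = seed + 1L)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest, images = if (is.null(dir)) images)
}

#' Stratified train/val/test split
#'
#' Assigns each specimen (manifest rows grouped by \code{id}) to a split,
#' per class, matching the fractions under floor-and-distribute rounding:
#' each split receives the floor of its share, and remainders go to the
#' splits with the largest fractional parts. Deterministic given the seed.
#'
#' @param manifest data.frame with columns \code{id} and \code{label}.
#' @param fractions named fractions summing to 1 (default 60/20/20).
#' @param seed RNG seed for the within-class permutation.
#' @return the manifest with its \code{split} column filled.
#' @export
stratifiedSplit <- function(manifest, fractions = c(train = 0.6, val = 0.2,
                                                    test = 0.2),
                            seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  splits <- names(fractions)
  manifest$split <- NA_character_
  withSeed(seed, {
    for (cl in unique(manifest$label)) {
      ids <- unique(manifest$id[manifest$label == cl])
      n <- length(ids)
      shares <- fractions * n
      base <- floor(shares)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(shares - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      ids <- sample(ids)
      assign <- rep(splits, times = base)
      for (k in seq_along(ids))
        manifest$split[manifest$id == ids[k]] <- assign[k]
    }
  })
  manifest
}

## ---- image I/O -------------------------------------------------------------

#' Write an image as 8-bit PNG
#' @param image (H, W, 3) array, values 0--255.
#' @param path output file path.
#' @export
writePeelImage <- function(image, path) {
  e <- EBImage::Image(aperm(image, c(2, 1, 3)) / 255, colormode = "Color")
  EBImage::writeImage(e, path, type = "png", bits = 8L)
  invisible(path)
}

#' Read a PNG image as an (H, W, 3) array with values 0--255
#' @param path PNG file path.
#' @export
readPeelImage <- function(path) {
  e <- EBImage::readImage(path)
  a <- as.array(e)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  aperm(a, c(2, 1, 3)) * 255
}

#' Resize a color image with bilinear interpolation
#' @param image (H, W, 3) array, values 0--255.
#' @param size target square side in pixels.
#' @return (size, size, 3) array.
#' @export
resizeImage <- function(image, size) {
  e <- EBImage::Image(aperm(image, c(2, 1, 3)) / 255, colormode = "Color")
  r <- EBImage::resize(e, w = size, h = size)
  out <- aperm(as.array(r), c(2, 1, 3)) * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}
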