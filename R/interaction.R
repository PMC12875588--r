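# Channel-level feature interaction between the three branches.
#
# A feature map is an array whose third dimension indexes channels:
# (h, w, C) for a single sample or (h, w, C, N) for a batch. Channel indices
# are 1-based.

#' Replace channels of a feature map with those of another
#'
#' Channels listed in \code{idx} are copied from \code{source}; all other
#' channels are kept from \code{target}. Inputs are not modified.
#'
#' @param target,source feature maps of identical shape, (h, w, C) or
#'   (h, w, C, N).
#' @param idx integer vector of distinct 1-based channel indices (may be
#'   empty).
#' @return feature map of the same shape.
#' @export
replaceChannels <- function(target, source, idx) {
  if (!identical(dim(target), dim(source)))
    stop("feature maps are shape-incompatible")
  if (length(idx) == 0L) return(target)
  C <- dim(target)[3]
  idx <- as.integer(idx)
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > C))
    stop("invalid channel index set")
  out <- target
  if (length(dim(target)) == 3L) {
    out[, , idx] <- source[, , idx]
  } else {
    out[, , idx, ] <- source[, , idx, ]
  }
  out
}

#' Sample a random channel-index set
#'
#' Draws \code{floor(ratio * C)} distinct channel indices uniformly without
#' replacement from \code{1:C}, using R's current RNG stream (seed with
#' \code{set.seed} for reproducibility).
#'
#' @param C channel count.
#' @param ratio fraction of channels in [0, 1].
#' @return integer vector of distinct 1-based indices.
#' @examples
#' set.seed(1); sampleChannelIndices(512, 0.10)  # 51 indices
#' @export
sampleChannelIndices <- function(C, ratio) {
  stopifnot(ratio >= 0, ratio <= 1, C >= 1)
  m <- floor(ratio * C)
  if (m == 0L) return(integer(0))
  sort(sample.int(C, m))
}

#' Forward interaction phase: full branch into local branches
#'
#' One shared index set covering \code{forwardRatio} of the full-branch
#' channels is drawn, and those channels of \code{F} are injected into both
#' the exocarp map \code{E} and the albedo map \code{A}.
#'
#' @param F,E,A shape-compatible feature maps (full, exocarp, albedo).
#' @param config an \linkS4class{InteractionConfig}.
#' @return list with the updated maps \code{E}, \code{A} and the drawn index
#'   set \code{idx}.
#' @export
interactionForward <- function(F, E, A, config = interactionConfig()) {
  if (!config@active)
    return(list(E = E, A = A, idx = integer(0)))
  idx <- sampleChannelIndices(dim(F)[3], config@forwardRatio)
  list(E = replaceChannels(E, F, idx),
       A = replaceChannels(A, F, idx),
       idx = idx)
}

#' Reverse interaction phase: local branches back into the full branch
#'
#' Two independent index sets of \code{reverseRatio} of the channels are
#' drawn; exocarp channels are injected first, then albedo channels (which
#' may overwrite exocarp-injected channels where the sets intersect). By
#' default the forward-updated local maps are injected; set
#' \code{reverseUsesOriginal} in the config (and pass \code{origE},
#' \code{origA}) to inject the pre-interaction maps instead.
#'
#' @param F full-branch feature map.
#' @param E,A (updated) exocarp and albedo maps.
#' @param config an \linkS4class{InteractionConfig}.
#' @param origE,origA pre-interaction local maps, used only when
#'   \code{config@reverseUsesOriginal} is TRUE.
#' @return list with the updated \code{F} and the index sets \code{idxE},
#'   \code{idxA}.
#' @export
interactionReverse <- function(F, E, A, config = interactionConfig(),
                               origE = NULL, origA = NULL) {
  if (!config@active)
    return(list(F = F, idxE = integer(0), idxA = integer(0)))
  srcE <- if (config@reverseUsesOriginal && !is.null(origE)) origE else E
  srcA <- if (config@reverseUsesOriginal && !is.null(origA)) origA else A
  C <- dim(F)[3]
  idxE <- sampleChannelIndices(C, config@reverseRatio)
  idxA <- sampleChannelIndices(C, config@reverseRatio)
  F1 <- replaceChannels(F, srcE, idxE)
  list(F = replaceChannels(F1, srcA, idxA), idxE = idxE, idxA = idxA)
}
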