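#' AttributionMap: gradient-times-input over the behavioral space
#'
#' Signed 50x50 maps showing which JID regions drive one model output
#' channel up (positive) or down (negative), for the all-ITI and Social
#' feature spaces, averaged over the 9 context bins and over the
#' evaluated windows.
#'
#' @slot all 50x50 signed matrix for the all-ITI input channel.
#' @slot social 50x50 signed matrix for the Social input channel.
#' @slot channel label of the attributed output channel.
#' @slot nWindows number of windows averaged.
#' @exportClass AttributionMap
setClass("AttributionMap",
  representation(all = "matrix", social = "matrix", channel = "character",
                 nWindows = "integer"))

setMethod("show", "AttributionMap", function(object) {
  cat(sprintf(
    "AttributionMap for channel %s over %d windows (all-ITI range [%.2e, %.2e])\n",
    object@channel, object@nWindows, min(object@all), max(object@all)))
})

#' Attribute model output to JID regions by gradient * input
#'
#' Differentiates a scalar summary of the model's mixture output -- the
#' mean of the dominant (largest-weight) component, a differentiable
#' stand-in for the grid-searched mode -- with respect to the 9x50x50x2
#' input window, multiplies elementwise by the input, and averages over
#' the 9 context bins and over windows. By construction a zero input
#' pixel receives zero attribution. Windows averaged are the test-split
#' windows with at least one present context bin (mirroring evaluation
#' masking) unless \code{subset} says otherwise.
#'
#' @param model a trained [JidModel-class].
#' @param windows a [ContextWindowSet-class].
#' @param channel output channel index or label.
#' @param subset \code{"test"} (default), \code{"train"}, or \code{"all"}.
#' @param batchSize windows per forward/backward pass.
#' @return an [AttributionMap-class].
#' @export
gradientTimesInput <- function(model, windows, channel = 1L,
                               subset = c("test", "train", "all"),
                               batchSize = 64L) {
  if (!model@trained) stop("model is not trained")
  subset <- match.arg(subset)
  cfg <- model@config
  C <- cfg$nOutputChannels; K <- cfg$nMixture
  if (is.character(channel))
    channel <- match(channel, windows@targetInfo$label)
  if (is.na(channel) || channel < 1L || channel > C)
    stop("unknown output channel")
  keep <- switch(subset, test = !windows@isTrain, train = windows@isTrain,
                 all = rep(TRUE, length(windows@isTrain)))
  idx <- which(keep & windows@anyPresent)
  if (!length(idx)) stop("no windows to attribute")
  acc <- numeric(5000L)
  featPad <- cbind(windows@features, 0)
  for (i0 in seq(1L, length(idx), by = batchSize)) {
    rows <- idx[i0:min(length(idx), i0 + batchSize - 1L)]
    B <- length(rows)
    fh <- windows@frameHours[rows, , drop = FALSE]
    # frames are NOT deduplicated: each window needs its own input gradient
    Xf <- t(featPad[, as.vector(fh), drop = FALSE])    # (B*9) x 5000
    map <- matrix(seq_len(B * 9L), B, 9L)
    fwd <- nn_forward(cfg, model@params, model@state, Xf, map,
                      train = FALSE)
    cols <- (channel - 1L) * 3L * K + seq_len(3L * K)
    mix <- raw_to_mixture(fwd$raw[, cols, drop = FALSE], K)
    jstar <- max.col(mix$weights, ties.method = "first")
    dRaw <- matrix(0, B, ncol(fwd$raw))
    dRaw[cbind(seq_len(B), (channel - 1L) * 3L * K + jstar)] <- 1
    bk <- nn_backward(cfg, model@params, fwd, dRaw, map, B * 9L,
                      needInputGrad = TRUE, train = FALSE)
    gx <- bk$dInput * Xf                               # (B*9) x 5000
    # mean over the 9 bins per window, then sum over windows
    acc <- acc + colSums(gx) / 9
  }
  acc <- acc / length(idx)
  new("AttributionMap",
      all = matrix(acc[1:2500], 50, 50),
      social = matrix(acc[2501:5000], 50, 50),
      channel = windows@targetInfo$label[channel],
      nWindows = length(idx))
}
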