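# The convolutional-recurrent mixture-density model: a shared per-frame
# extractor over the 9-hour behavioral context, a 3-layer LSTM(50), and a
# per-channel linear head emitting 3-component Gaussian mixture parameters.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

SIGMA_FLOOR <- 1e-3

extractor_layers <- function(extractor, batchNorm = TRUE) {
  bn <- function(name, npos, c)
    if (batchNorm) list(make_bn(name, npos, c)) else list()
  if (extractor == "small") {
    ch <- c(2L, 8L, 16L, 24L, 32L)
    sz <- c(50L, 25L, 13L, 7L, 4L)
    layers <- list()
    for (i in 1:4) {
      layers <- c(layers,
        list(make_conv(paste0("c", i), sz[i], sz[i], ch[i], ch[i + 1],
                       k = 3L, stride = 2L, pad = 1L,
                       bias = !batchNorm)),
        bn(paste0("b", i), sz[i + 1]^2, ch[i + 1]),
        list(make_relu()))
    }
    c(layers, list(make_dense("fc", sz[5]^2 * ch[5], 128L, relu = TRUE)))
  } else if (extractor == "resnet50") {
    bottleneck <- function(name, hw, cin, cmid, cout, stride) {
      ho <- (hw - 1L) %/% stride + 1L
      main <- c(
        list(make_conv(paste0(name, ".a"), hw, hw, cin, cmid, k = 1L,
                       stride = stride, pad = 0L, bias = !batchNorm)),
        bn(paste0(name, ".abn"), ho^2, cmid), list(make_relu()),
        list(make_conv(paste0(name, ".b"), ho, ho, cmid, cmid, k = 3L,
                       stride = 1L, pad = 1L, bias = !batchNorm)),
        bn(paste0(name, ".bbn"), ho^2, cmid), list(make_relu()),
        list(make_conv(paste0(name, ".c"), ho, ho, cmid, cout, k = 1L,
                       stride = 1L, pad = 0L, bias = !batchNorm)),
        bn(paste0(name, ".cbn"), ho^2, cout))
      proj <- if (cin != cout || stride != 1L)
        c(list(make_conv(paste0(name, ".p"), hw, hw, cin, cout, k = 1L,
                         stride = stride, pad = 0L, bias = !batchNorm)),
          bn(paste0(name, ".pbn"), ho^2, cout)) else NULL
      make_res(main, proj)
    }
    layers <- c(
      list(make_conv("stem", 50L, 50L, 2L, 64L, k = 3L, stride = 1L,
                     pad = 1L, bias = !batchNorm)),
      bn("stembn", 2500L, 64L), list(make_relu()))
    hw <- 50L; cin <- 64L
    stages <- list(c(3L, 64L, 256L, 1L), c(4L, 128L, 512L, 2L),
                   c(6L, 256L, 1024L, 2L), c(3L, 512L, 2048L, 2L))
    for (si in seq_along(stages)) {
      st <- stages[[si]]
      for (bi in seq_len(st[1])) {
        stride <- if (bi == 1L) st[4] else 1L
        layers <- c(layers, list(bottleneck(
          sprintf("s%db%d", si, bi), hw, cin, st[2], st[3], stride)))
        hw <- (hw - 1L) %/% stride + 1L
        cin <- st[3]
      }
    }
    c(layers, list(make_gap(hw^2, cin)),
      list(make_dense("emb", cin, 1024L, relu = TRUE)))
  } else stop("extractor must be 'small' or 'resnet50'")
}

embedding_dim <- function(extractor)
  if (extractor == "small") 128L else 1024L

#' Build an untrained conv-LSTM mixture-density model
#'
#' The extractor embeds each 50x50x2 hourly JID frame (shared weights
#' across the 9 context frames): either \code{"small"}, a 4-block strided
#' convolutional network with a 128-dimensional embedding suitable for
#' desk-scale experiments, or \code{"resnet50"}, a ResNet-50 bottleneck
#' architecture adapted to the 50x50x2 input (3x3 stride-1 stem, no
#' initial pooling) with a 1024-dimensional embedding per time step. The
#' sequence of embeddings feeds a 3-layer LSTM with 50 units; per output
#' channel a linear head emits 9 values (3 means, 3 standard deviations
#' via softplus, 3 mixture weights via softmax).
#'
#' @param nOutputChannels number of output channels: 2 per active
#'   detector (raw + 24-h-detrended), so one of 2, 4, 6, 8.
#' @param extractor \code{"small"} or \code{"resnet50"}.
#' @param nMixture mixture components per channel (default 3).
#' @param lstmUnits,lstmLayers recurrent size (defaults 50 and 3).
#' @param l2Conv l2 penalty on extractor weights.
#' @param l1Head l1 penalty on the mixture head weights.
#' @param dropoutRecurrent dropout probability between recurrent layers.
#' @param batchNorm use batch normalization in the extractor.
#' @param seed RNG seed for weight initialisation.
#' @return an untrained [JidModel-class].
#' @export
buildModel <- function(nOutputChannels, extractor = c("small", "resnet50"),
                       nMixture = 3L, lstmUnits = 50L, lstmLayers = 3L,
                       l2Conv = 0.001, l1Head = 0.001,
                       dropoutRecurrent = 0.4, batchNorm = TRUE,
                       seed = 1L) {
  extractor <- match.arg(extractor)
  if (!nOutputChannels %in% c(2L, 4L, 6L, 8L))
    stop("nOutputChannels must be one of 2, 4, 6, 8")
  set.seed(seed)
  layers <- extractor_layers(extractor, batchNorm)
  emb <- embedding_dim(extractor)
  params <- init_net_params(layers)
  params <- init_lstm_params(lstmLayers, emb, lstmUnits, params)
  nOut <- nOutputChannels * 3L * nMixture
  params$head.W <- matrix(stats::rnorm(lstmUnits * nOut, 0, 0.05),
                          lstmUnits, nOut)
  params$head.b <- numeric(nOut)
  cfg <- list(extractor = extractor, layers = layers, embeddingDim = emb,
              nOutputChannels = as.integer(nOutputChannels),
              nMixture = as.integer(nMixture),
              lstmUnits = as.integer(lstmUnits),
              lstmLayers = as.integer(lstmLayers), l2Conv = l2Conv,
              l1Head = l1Head, dropoutRecurrent = dropoutRecurrent,
              batchNorm = batchNorm, alignment = NA_character_)
  new("JidModel", config = cfg, params = params,
      state = init_net_state(layers), trained = FALSE,
      history = data.frame(), targetInfo = data.frame())
}

# mixture head ---------------------------------------------------------------

# raw head output for one channel -> mixture parameters
raw_to_mixture <- function(rawBlock, K) {
  list(means = rawBlock[, seq_len(K), drop = FALSE],
       sraw = rawBlock[, K + seq_len(K), drop = FALSE],
       stds = softplus(rawBlock[, K + seq_len(K), drop = FALSE]) +
         SIGMA_FLOOR,
       wraw = rawBlock[, 2 * K + seq_len(K), drop = FALSE],
       weights = {
         v <- rawBlock[, 2 * K + seq_len(K), drop = FALSE]
         e <- exp(v - apply(v, 1, max))
         e / rowSums(e)
       })
}

# per-row NLL and gradient wrt the raw block, vectorised over rows
mixture_nll_block <- function(mix, y) {
  mu <- mix$means; sg <- mix$stds; wv <- mix$weights
  z <- (y - mu) / sg
  logphi <- -0.918938533204673 - log(sg) - 0.5 * z^2
  a <- log(wv) + logphi
  m <- apply(a, 1, max)
  logS <- m + log(rowSums(exp(a - m)))
  r <- exp(a - logS)
  dmu <- -r * (y - mu) / sg^2
  dsg <- -r * ((y - mu)^2 / sg^3 - 1 / sg)
  dsraw <- dsg * sigm(mix$sraw)
  dwraw <- wv - r
  list(nll = -logS, dRaw = cbind(dmu, dsraw, dwraw))
}

#' Negative log-likelihood of a Gaussian mixture output
#'
#' \eqn{-\log \sum_i w_i N(y; \mu_i, \sigma_i)}, the per-hour training
#' objective of the mixture-density head.
#'
#' @param params list with numeric vectors \code{means}, \code{stds}
#'   (positive) and \code{weights} (nonnegative, summing to 1), one entry
#'   per mixture component.
#' @param target observed value (scalar or vector; vectors are evaluated
#'   elementwise and summed is not applied -- a vector of NLLs returns).
#' @return the NLL (same length as \code{target}).
#' @examples
#' mixtureNLL(list(means = c(0, 0, 0), stds = c(1, 1, 1),
#'                 weights = c(1, 0, 0)), 0)  # 0.5 * log(2*pi)
#' @export
mixtureNLL <- function(params, target) {
  mu <- params$means; sg <- params$stds; wv <- params$weights
  if (any(sg <= 0)) stop("mixture standard deviations must be positive")
  if (any(wv < 0) || abs(sum(wv) - 1) > 1e-8)
    stop("mixture weights must be nonnegative and sum to 1")
  vapply(target, function(y) {
    a <- log(wv) + stats::dnorm(y, mu, sg, log = TRUE)
    m <- max(a)
    -(m + log(sum(exp(a - m))))
  }, 0)
}

#' Maximum-likelihood point estimate from a Gaussian mixture
#'
#' Locates the mode of the mixture density by a dense grid search over
#' \code{[min(means) - 3*max(stds), max(means) + 3*max(stds)]} followed by
#' local refinement.
#'
#' @inheritParams mixtureNLL
#' @param gridPoints grid resolution for the initial search.
#' @return the mode (scalar).
#' @export
pointEstimate <- function(params, gridPoints = 501L) {
  mu <- params$means; sg <- params$stds; wv <- params$weights
  if (any(sg <= 0)) stop("mixture standard deviations must be positive")
  f <- function(x) vapply(x, function(xx)
    sum(wv * stats::dnorm(xx, mu, sg)), 0)
  lo <- min(mu) - 3 * max(sg); hi <- max(mu) + 3 * max(sg)
  if (lo == hi) return(lo)
  g <- seq(lo, hi, length.out = gridPoints)
  v <- f(g)
  i <- which.max(v)
  a <- g[max(1L, i - 1L)]; b <- g[min(gridPoints, i + 1L)]
  stats::optimize(f, c(a, b), maximum = TRUE, tol = 1e-10)$maximum
}

# context windows ------------------------------------------------------------

alignment_offsets <- function(alignment)
  if (alignment == "centered") -4:4 else -9:-1

#' Assemble model-ready context windows with leakage-free targets
#'
#' Pairs every hour that has a full 9-frame behavioral context and defined
#' detector counts with its per-channel targets: raw counts and their
#' 24-h-detrended counterparts, z-scored per channel on the training
#' split. The split is temporal (the test windows are the last
#' \code{1 - trainFrac} of target hours) and the detrending profile is
#' fitted on pre-split hours only, then applied everywhere.
#'
#' @param features an [HourlyFeatures-class].
#' @param counts a [DetectorSeries-class] on the same hour grid (error if
#'   misaligned).
#' @param alignment \code{"centered"} (frames t-4..t+4) or
#'   \code{"preceding"} (frames t-9..t-1, the time-causal variant).
#' @param trainFrac fraction of windows in the training split.
#' @param detrendMethod \code{"polynomial"} (default) or \code{"wavelet"}.
#' @param detrendDegree polynomial degree for the default method.
#' @return a [ContextWindowSet-class].
#' @export
makeContextWindows <- function(features, counts,
                               alignment = c("centered", "preceding"),
                               trainFrac = 0.8,
                               detrendMethod = c("polynomial", "wavelet"),
                               detrendDegree = 5L) {
  alignment <- match.arg(alignment)
  detrendMethod <- match.arg(detrendMethod)
  if (!identical(hourIndex(features), hourIndex(counts)))
    stop("features and counts are on different hour grids")
  H <- ncol(features)
  offs <- alignment_offsets(alignment)
  tcols <- seq_len(H)
  tcols <- tcols[tcols + min(offs) >= 1L & tcols + max(offs) <= H]
  cts <- detectorCounts(counts)
  ok <- colSums(is.na(cts[, tcols, drop = FALSE])) == 0
  tcols <- tcols[ok]
  n <- length(tcols)
  if (n < 2L) stop("not enough complete windows")
  nTrain <- max(1L, floor(n * trainFrac))
  isTrain <- seq_len(n) <= nTrain
  splitCol <- if (nTrain < n) tcols[nTrain + 1L] else H + 1L
  fitHours <- seq_len(H) < splitCol
  det <- if (detrendMethod == "polynomial")
    polynomialDetrend(counts, detrendDegree, fitHours)
  else waveletDetrend(counts)
  res <- detrendResidual(det)
  D <- nrow(cts)
  labs <- if (!is.null(rownames(cts))) rownames(cts)
          else paste0("det", seq_len(D))
  tmats <- vector("list", 2L * D)
  info <- data.frame(label = character(2 * D), detector = character(2 * D),
                     type = character(2 * D), mean = numeric(2 * D),
                     sd = numeric(2 * D), stringsAsFactors = FALSE)
  for (d in seq_len(D)) {
    for (tt in 1:2) {
      idx <- (tt - 1L) * D + d
      y <- if (tt == 1L) cts[d, tcols] else res[d, tcols]
      mu <- mean(y[isTrain]); sdv <- stats::sd(y[isTrain])
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      tmats[[idx]] <- (y - mu) / sdv
      info$label[idx] <- paste0(labs[d],
                                if (tt == 1L) ".raw" else ".detrended")
      info$detector[idx] <- labs[d]
      info$type[idx] <- if (tt == 1L) "raw" else "detrended"
      info$mean[idx] <- mu; info$sd[idx] <- sdv
    }
  }
  targets <- do.call(cbind, tmats)
  colnames(targets) <- info$label
  feat <- rbind(jidAll(features), jidSocial(features))
  presence <- cbind(all = colData(features)$presentAll,
                    social = colData(features)$presentSocial)
  frameHours <- outer(tcols, offs, `+`)
  anyPresent <- matrix(presence[, "all"][frameHours],
                       nrow = n)
  anyPresent <- rowSums(anyPresent) > 0
  new("ContextWindowSet", features = feat, presence = presence,
      hourIndex = as.integer(hourIndex(features)),
      targetHour = as.integer(hourIndex(features)[tcols]),
      frameHours = frameHours, targets = targets, targetInfo = info,
      alignment = alignment, isTrain = isTrain, anyPresent = anyPresent)
}

# forward/backward through the whole network ---------------------------------

nn_forward <- function(cfg, params, state, Xf, map, train = FALSE) {
  ext <- net_forward(cfg$layers, Xf, params, state, train)
  Xs <- lapply(seq_len(ncol(map)), function(t)
    ext$out[map[, t], , drop = FALSE])
  fw <- lstm_forward(Xs, params, cfg$lstmLayers, cfg$lstmUnits,
                     cfg$dropoutRecurrent, train)
  raw <- fw$hFinal %*% params$head.W
  raw <- raw + rep(params$head.b, each = nrow(raw))
  list(raw = raw, ext = ext, fw = fw, state = ext$state)
}

nn_backward <- function(cfg, params, fwd, dRaw, map, nf,
                        needInputGrad = FALSE, train = FALSE) {
  grads <- list(head.W = crossprod(fwd$fw$hFinal, dRaw),
                head.b = colSums(dRaw))
  dH <- dRaw %*% t(params$head.W)
  lb <- lstm_backward(fwd$fw, dH, params, cfg$lstmLayers, cfg$lstmUnits,
                      cfg$dropoutRecurrent, train)
  grads <- c(grads, lb$grads)
  big <- do.call(rbind, lb$dInputs)
  grp <- as.vector(map)
  agg <- rowsum(big, grp)
  dE <- matrix(0, nf, cfg$embeddingDim)
  dE[as.integer(rownames(agg)), ] <- agg
  eb <- net_backward(cfg$layers, fwd$ext$caches, dE, params)
  grads <- c(grads, eb$grads)
  list(grads = grads, dInput = if (needInputGrad) eb$dIn else NULL)
}

# loss and gradient on the raw head output over all channels
mixture_loss <- function(raw, targets, C, K) {
  n <- nrow(raw)
  dRaw <- matrix(0, n, ncol(raw))
  nll <- matrix(0, n, C)
  for (cc in seq_len(C)) {
    cols <- (cc - 1L) * 3L * K + seq_len(3L * K)
    mix <- raw_to_mixture(raw[, cols, drop = FALSE], K)
    r <- mixture_nll_block(mix, targets[, cc])
    nll[, cc] <- r$nll
    dRaw[, cols] <- r$dRaw
  }
  list(loss = mean(nll), dRaw = dRaw / (n * C))
}

extractor_weight_names <- function(cfg) {
  nms <- character()
  walk <- function(ls) for (l in ls) {
    if (l$type %in% c("conv", "dense"))
      nms <<- c(nms, paste0(l$name, ".W"))
    else if (l$type == "res") {
      walk(l$main); if (!is.null(l$proj)) walk(l$proj)
    }
  }
  walk(cfg$layers)
  nms
}

#' Train the model on a context-window set
#'
#' Minimises the mean mixture negative log-likelihood over the training
#' windows with Adam. Batches are contiguous blocks of target hours whose
#' order is shuffled each epoch: consecutive windows share 8 of their 9
#' frames, so the shared extractor is evaluated once per distinct hour per
#' batch. l2 regularisation applies to extractor weights and l1 to the
#' head, matching the model definition. Validation loss is the mixture
#' NLL on the held-out (later) windows.
#'
#' @param model an untrained (or previously trained) [JidModel-class].
#' @param windows a [ContextWindowSet-class]; its channel count must match
#'   the model's.
#' @param epochs training epochs.
#' @param batchSize windows per block.
#' @param learningRate Adam learning rate.
#' @param seed RNG seed (batch order, dropout).
#' @param verbose print per-epoch losses.
#' @return the trained [JidModel-class] with \code{history} filled in.
#' @export
trainModel <- function(model, windows, epochs = 100L, batchSize = 64L,
                       learningRate = 1e-3, seed = 1L, verbose = FALSE) {
  cfg <- model@config
  C <- cfg$nOutputChannels; K <- cfg$nMixture
  if (ncol(windows@targets) != C)
    stop(sprintf("window set has %d channels but model expects %d",
                 ncol(windows@targets), C))
  trIdx <- which(windows@isTrain)
  if (!length(trIdx)) stop("no training windows")
  teIdx <- which(!windows@isTrain)
  set.seed(seed)
  params <- model@params
  state <- model@state
  extW <- extractor_weight_names(cfg)
  adamM <- lapply(params, function(p) p * 0)
  adamV <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; tAdam <- 0
  featPad <- cbind(windows@features, 0)  # last column = zero frame
  blocks <- split(trIdx, ceiling(seq_along(trIdx) / batchSize))
  hist <- data.frame(epoch = integer(), train = numeric(),
                     validation = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(blocks))
    epLoss <- 0; epN <- 0
    for (bi in ord) {
      rows <- blocks[[bi]]
      fh <- windows@frameHours[rows, , drop = FALSE]
      uf <- sort(unique(as.vector(fh)))
      Xf <- t(featPad[, uf, drop = FALSE])
      map <- matrix(match(fh, uf), nrow(fh), ncol(fh))
      fwd <- nn_forward(cfg, params, state, Xf, map, train = TRUE)
      state <- fwd$state
      ml <- mixture_loss(fwd$raw, windows@targets[rows, , drop = FALSE],
                         C, K)
      epLoss <- epLoss + ml$loss * length(rows); epN <- epN + length(rows)
      bk <- nn_backward(cfg, params, fwd, ml$dRaw, map, length(uf),
                        train = TRUE)
      g <- bk$grads
      for (nm in extW) g[[nm]] <- g[[nm]] + 2 * cfg$l2Conv * params[[nm]]
      g$head.W <- g$head.W + cfg$l1Head * sign(params$head.W)
      tAdam <- tAdam + 1
      corr <- sqrt(1 - b2^tAdam) / (1 - b1^tAdam)
      for (nm in names(g)) {
        adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * g[[nm]]
        adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * g[[nm]]^2
        params[[nm]] <- params[[nm]] -
          learningRate * corr * adamM[[nm]] / (sqrt(adamV[[nm]]) + epsA)
      }
    }
    val <- NA_real_
    if (length(teIdx)) {
      vr <- forward_windows(cfg, params, state, windows, teIdx,
                            featPad = featPad)
      val <- mixture_loss(vr, windows@targets[teIdx, , drop = FALSE],
                          C, K)$loss
    }
    hist <- rbind(hist, data.frame(epoch = ep, train = epLoss / epN,
                                   validation = val))
    if (verbose)
      message(sprintf("epoch %d: train NLL %.4f, validation NLL %.4f",
                      ep, epLoss / epN, val))
  }
  model@params <- params
  model@state <- state
  model@trained <- TRUE
  model@history <- hist
  model@targetInfo <- windows@targetInfo
  model@config$alignment <- windows@alignment
  model
}

# evaluation-mode forward over a set of windows; returns the raw head output
forward_windows <- function(cfg, params, state, windows, idx,
                            chunk = 512L, featPad = NULL) {
  if (is.null(featPad)) featPad <- cbind(windows@features, 0)
  out <- NULL
  for (i0 in seq(1L, length(idx), by = chunk)) {
    rows <- idx[i0:min(length(idx), i0 + chunk - 1L)]
    fh <- windows@frameHours[rows, , drop = FALSE]
    uf <- sort(unique(as.vector(fh)))
    Xf <- t(featPad[, uf, drop = FALSE])
    map <- matrix(match(fh, uf), nrow(fh), ncol(fh))
    fwd <- nn_forward(cfg, params, state, Xf, map, train = FALSE)
    out <- rbind(out, fwd$raw)
  }
  out
}

# point estimates (z-scale) per channel from raw head outputs
point_estimates_raw <- function(raw, C, K) {
  n <- nrow(raw)
  est <- matrix(0, n, C)
  for (cc in seq_len(C)) {
    cols <- (cc - 1L) * 3L * K + seq_len(3L * K)
    mix <- raw_to_mixture(raw[, cols, drop = FALSE], K)
    est[, cc] <- vapply(seq_len(n), function(i)
      pointEstimate(list(means = mix$means[i, ], stds = mix$stds[i, ],
                         weights = mix$weights[i, ])), 0)
  }
  est
}

#' Predict the hourly series from behavioral features
#'
#' Runs the trained model over every hour of a feature series (frames
#' outside the recorded span are zero-filled). Hours whose full 9-frame
#' context carries no behavioral data are flagged \code{allAbsent}: their
#' prediction collapses toward the model's unconditional output and
#' evaluation should exclude them.
#'
#' @param model a trained [JidModel-class].
#' @param features an [HourlyFeatures-class].
#' @return a \linkS4class{SummarizedExperiment}: assays \code{estimate}
#'   (count scale) and \code{estimateZ} (z-scale), rows = output channels,
#'   columns = hours; \code{colData} has \code{hourIndex} and
#'   \code{allAbsent}; \code{metadata()$mixture} is the hours x (9 x
#'   channels) raw mixture parameter matrix.
#' @export
predictSeries <- function(model, features) {
  if (!model@trained) stop("model is not trained")
  cfg <- model@config
  C <- cfg$nOutputChannels; K <- cfg$nMixture
  offs <- alignment_offsets(cfg$alignment)
  H <- ncol(features)
  feat <- rbind(jidAll(features), jidSocial(features))
  featPad <- cbind(feat, 0)
  presAll <- colData(features)$presentAll
  fh <- outer(seq_len(H), offs, `+`)
  fh[fh < 1L | fh > H] <- H + 1L  # zero frame
  presPad <- c(presAll, FALSE)
  allAbsent <- rowSums(matrix(presPad[fh], nrow = H)) == 0
  raw <- NULL
  chunk <- 512L
  for (i0 in seq(1L, H, by = chunk)) {
    rows <- i0:min(H, i0 + chunk - 1L)
    sub <- fh[rows, , drop = FALSE]
    uf <- sort(unique(as.vector(sub)))
    Xf <- t(featPad[, uf, drop = FALSE])
    map <- matrix(match(sub, uf), nrow(sub), ncol(sub))
    fwd <- nn_forward(cfg, model@params, model@state, Xf, map,
                      train = FALSE)
    raw <- rbind(raw, fwd$raw)
  }
  estZ <- t(point_estimates_raw(raw, C, K))
  info <- model@targetInfo
  est <- estZ * info$sd + info$mean
  rownames(est) <- rownames(estZ) <- info$label
  se <- SummarizedExperiment(
    assays = list(estimate = est, estimateZ = estZ),
    rowData = DataFrame(info),
    colData = DataFrame(hourIndex = hourIndex(features),
                        allAbsent = allAbsent))
  metadata(se)$mixture <- raw
  se
}
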