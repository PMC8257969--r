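# Stacked LSTM with manual backpropagation through time.
# Gate layout in the 4u-wide pre-activation: input, forget, cell, output.

sigm <- function(x) 1 / (1 + exp(-x))

init_lstm_params <- function(nLayers, din, units, params) {
  for (l in seq_len(nLayers)) {
    d <- if (l == 1L) din else units
    r <- sqrt(1 / d)
    params[[sprintf("lstm%d.W", l)]] <-
      matrix(stats::runif(d * 4 * units, -r, r), d, 4 * units)
    r2 <- sqrt(1 / units)
    params[[sprintf("lstm%d.U", l)]] <-
      matrix(stats::runif(units * 4 * units, -r2, r2), units, 4 * units)
    b <- numeric(4 * units)
    b[units + seq_len(units)] <- 1  # forget-gate bias
    params[[sprintf("lstm%d.b", l)]] <- b
  }
  params
}

# Xs: list of T matrices (n x din). Returns final hidden state of the top
# layer plus the caches needed for backward.
lstm_forward <- function(Xs, params, nLayers, units, dropout = 0,
                         train = FALSE) {
  n <- nrow(Xs[[1]])
  Tn <- length(Xs)
  caches <- vector("list", nLayers)
  masks <- vector("list", nLayers)
  inp <- Xs
  for (l in seq_len(nLayers)) {
    W <- params[[sprintf("lstm%d.W", l)]]
    U <- params[[sprintf("lstm%d.U", l)]]
    b <- params[[sprintf("lstm%d.b", l)]]
    h <- matrix(0, n, units); cs <- matrix(0, n, units)
    st <- vector("list", Tn)
    out <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      A <- inp[[t]] %*% W + h %*% U
      A <- A + rep(b, each = n)
      iu <- seq_len(units)
      gi <- sigm(A[, iu, drop = FALSE])
      gf <- sigm(A[, units + iu, drop = FALSE])
      gg <- tanh(A[, 2 * units + iu, drop = FALSE])
      go <- sigm(A[, 3 * units + iu, drop = FALSE])
      cNew <- gf * cs + gi * gg
      tc <- tanh(cNew)
      hNew <- go * tc
      st[[t]] <- list(x = inp[[t]], hprev = h, cprev = cs, i = gi, f = gf,
                      g = gg, o = go, tc = tc)
      h <- hNew; cs <- cNew
      out[[t]] <- hNew
    }
    caches[[l]] <- st
    if (l < nLayers && dropout > 0 && train) {
      masks[[l]] <- lapply(seq_len(Tn), function(t)
        matrix(stats::rbinom(n * units, 1L, 1 - dropout) / (1 - dropout),
               n, units))
      out <- lapply(seq_len(Tn), function(t) out[[t]] * masks[[l]][[t]])
    }
    inp <- out
  }
  list(hFinal = inp[[Tn]], caches = caches, masks = masks, n = n, Tn = Tn)
}

# dHFinal: gradient on the top layer's final hidden state. Returns grads on
# the LSTM parameters and on the input sequence (list of T matrices).
lstm_backward <- function(fw, dHFinal, params, nLayers, units,
                          dropout = 0, train = FALSE) {
  n <- fw$n; Tn <- fw$Tn
  grads <- list()
  # upstream gradient on each layer's output sequence
  dOutSeq <- vector("list", Tn)
  for (t in seq_len(Tn)) dOutSeq[[t]] <- matrix(0, n, units)
  dOutSeq[[Tn]] <- dHFinal
  for (l in rev(seq_len(nLayers))) {
    W <- params[[sprintf("lstm%d.W", l)]]
    U <- params[[sprintf("lstm%d.U", l)]]
    st <- fw$caches[[l]]
    din <- nrow(W)
    dW <- matrix(0, din, 4 * units)
    dU <- matrix(0, units, 4 * units)
    db <- numeric(4 * units)
    dXs <- vector("list", Tn)
    dh <- matrix(0, n, units)
    dc <- matrix(0, n, units)
    for (t in rev(seq_len(Tn))) {
      dh <- dh + dOutSeq[[t]]
      s <- st[[t]]
      dc <- dc + dh * s$o * (1 - s$tc^2)
      dgo <- dh * s$tc
      dgi <- dc * s$g
      dgg <- dc * s$i
      dgf <- dc * s$cprev
      dA <- matrix(0, n, 4 * units)
      iu <- seq_len(units)
      dA[, iu] <- dgi * s$i * (1 - s$i)
      dA[, units + iu] <- dgf * s$f * (1 - s$f)
      dA[, 2 * units + iu] <- dgg * (1 - s$g^2)
      dA[, 3 * units + iu] <- dgo * s$o * (1 - s$o)
      dW <- dW + crossprod(s$x, dA)
      dU <- dU + crossprod(s$hprev, dA)
      db <- db + colSums(dA)
      dXs[[t]] <- dA %*% t(W)
      dh <- dA %*% t(U)
      dc <- dc * s$f
    }
    grads[[sprintf("lstm%d.W", l)]] <- dW
    grads[[sprintf("lstm%d.U", l)]] <- dU
    grads[[sprintf("lstm%d.b", l)]] <- db
    if (l > 1L) {
      if (dropout > 0 && train && !is.null(fw$masks[[l - 1L]]))
        for (t in seq_len(Tn)) dXs[[t]] <- dXs[[t]] * fw$masks[[l - 1L]][[t]]
      dOutSeq <- dXs
    } else {
      return(list(grads = grads, dInputs = dXs))
    }
  }
}
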