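# Minimal BLAS-backed neural-network engine.
#
# Activations for image-like data are stored as n x (h*w*c) matrices,
# column-major over (y, x, channel), i.e. the vectorised R array (h, w, c)
# per sample. Convolution is im2col + dgemm; the col2im scatter in the
# backward pass is a precomputed sparse matrix product. All shapes and
# index maps are computed once when a layer is created.

#' @importFrom Matrix sparseMatrix
NULL

make_conv <- function(name, hin, win, cin, cout, k = 3L, stride = 1L,
                      pad = 1L, bias = TRUE) {
  hp <- hin + 2L * pad; wp <- win + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  npos <- ho * wo
  patch <- k * k * cin
  # interior of the padded frame, in input layout order
  padMap <- as.vector(outer(seq_len(hin) + pad,
    (outer(seq_len(win) + pad, seq_len(cin) - 1L,
           function(x, cc) (cc * wp + x - 1L) * hp)), `+`))
  # patch offsets in (dy, dx, cc) order; output origins in (oy, ox) order
  base <- as.vector(outer(seq_len(k),
    (outer(seq_len(k) - 1L, seq_len(cin) - 1L,
           function(dx, cc) (cc * wp + dx) * hp)), `+`))
  origin <- as.vector(outer((seq_len(ho) - 1L) * stride,
                            (seq_len(wo) - 1L) * stride * hp, `+`))
  # position-major layout: cols gathered with this index reshape to
  # (n*npos, patch) without any transposition
  idx <- as.integer(outer(origin, base, `+`))
  scatter <- sparseMatrix(i = seq_along(idx), j = idx, x = 1,
                          dims = c(length(idx), hp * wp * cin))
  list(type = "conv", name = name, hin = hin, win = win, cin = cin,
       cout = cout, k = k, stride = stride, pad = pad, ho = ho, wo = wo,
       npos = npos, patch = patch, lp = hp * wp * cin, padMap = padMap,
       idx = idx, scatter = scatter, bias = bias,
       outLen = npos * cout, outShape = c(ho, wo, cout))
}

make_bn <- function(name, npos, c)
  list(type = "bn", name = name, npos = npos, c = c, eps = 1e-5,
       momentum = 0.9)

make_relu <- function() list(type = "relu")

make_dense <- function(name, din, dout, relu = FALSE)
  list(type = "dense", name = name, din = din, dout = dout, relu = relu)

make_gap <- function(npos, c) list(type = "gap", npos = npos, c = c)

make_res <- function(main, proj = NULL) {
  list(type = "res", main = main, proj = proj)
}

# parameter initialisation ---------------------------------------------------

init_layer_params <- function(layer, params) {
  switch(layer$type,
    conv = {
      fan <- layer$patch
      params[[paste0(layer$name, ".W")]] <-
        matrix(stats::rnorm(fan * layer$cout, 0, sqrt(2 / fan)), fan,
               layer$cout)
      if (layer$bias) params[[paste0(layer$name, ".b")]] <-
        numeric(layer$cout)
    },
    bn = {
      params[[paste0(layer$name, ".gamma")]] <- rep(1, layer$c)
      params[[paste0(layer$name, ".beta")]] <- numeric(layer$c)
    },
    dense = {
      fan <- layer$din
      params[[paste0(layer$name, ".W")]] <-
        matrix(stats::rnorm(fan * layer$dout, 0, sqrt(2 / fan)), fan,
               layer$dout)
      params[[paste0(layer$name, ".b")]] <- numeric(layer$dout)
    },
    res = {
      for (l in layer$main) params <- init_layer_params(l, params)
      if (!is.null(layer$proj))
        for (l in layer$proj) params <- init_layer_params(l, params)
    },
    params)
  if (layer$type %in% c("conv", "bn", "dense")) params else params
}

init_net_params <- function(layers) {
  params <- list()
  for (l in layers) params <- init_layer_params(l, params)
  params
}

init_net_state <- function(layers) {
  state <- list()
  walk <- function(ls) for (l in ls) {
    if (l$type == "bn") {
      state[[paste0(l$name, ".rmean")]] <<- numeric(l$c)
      state[[paste0(l$name, ".rvar")]] <<- rep(1, l$c)
    } else if (l$type == "res") {
      walk(l$main); if (!is.null(l$proj)) walk(l$proj)
    }
  }
  walk(layers)
  state
}

# forward / backward ---------------------------------------------------------

conv_forward <- function(layer, X, params) {
  n <- nrow(X)
  Xpad <- matrix(0, n, layer$lp)
  Xpad[, layer$padMap] <- X
  M <- Xpad[, layer$idx, drop = FALSE]   # (n, npos*patch), position-major
  dim(M) <- c(n * layer$npos, layer$patch)
  W <- params[[paste0(layer$name, ".W")]]
  Y <- M %*% W
  if (layer$bias)
    Y <- Y + rep(params[[paste0(layer$name, ".b")]],
                 each = n * layer$npos)
  dim(Y) <- c(n, layer$outLen)
  list(out = Y, cache = list(M = M, n = n))
}

conv_backward <- function(layer, cache, dOut, params) {
  n <- cache$n
  W <- params[[paste0(layer$name, ".W")]]
  dY <- dOut
  dim(dY) <- c(n * layer$npos, layer$cout)
  grads <- list()
  grads[[paste0(layer$name, ".W")]] <- crossprod(cache$M, dY)
  if (layer$bias) grads[[paste0(layer$name, ".b")]] <- colSums(dY)
  dM <- dY %*% t(W)
  dim(dM) <- c(n, layer$npos * layer$patch)
  dXpad <- as.matrix(dM %*% layer$scatter)
  list(dIn = dXpad[, layer$padMap, drop = FALSE], grads = grads)
}

bn_forward <- function(layer, X, params, state, train) {
  n <- nrow(X)
  g <- params[[paste0(layer$name, ".gamma")]]
  b <- params[[paste0(layer$name, ".beta")]]
  Xr <- X
  dim(Xr) <- c(n * layer$npos, layer$c)
  if (train) {
    mu <- colMeans(Xr)
    xc <- Xr - rep(mu, each = nrow(Xr))
    v <- colMeans(xc^2)
    state[[paste0(layer$name, ".rmean")]] <-
      layer$momentum * state[[paste0(layer$name, ".rmean")]] +
      (1 - layer$momentum) * mu
    state[[paste0(layer$name, ".rvar")]] <-
      layer$momentum * state[[paste0(layer$name, ".rvar")]] +
      (1 - layer$momentum) * v
  } else {
    mu <- state[[paste0(layer$name, ".rmean")]]
    v <- state[[paste0(layer$name, ".rvar")]]
    xc <- Xr - rep(mu, each = nrow(Xr))
  }
  istd <- 1 / sqrt(v + layer$eps)
  m <- nrow(Xr)
  xhat <- xc * rep(istd, each = m)
  Y <- xhat * rep(g, each = m) + rep(b, each = m)
  dim(Y) <- c(n, layer$npos * layer$c)
  list(out = Y, cache = list(xhat = xhat, istd = istd, n = n, train = train),
       state = state)
}

bn_backward <- function(layer, cache, dOut, params) {
  n <- cache$n
  g <- params[[paste0(layer$name, ".gamma")]]
  dY <- dOut
  dim(dY) <- c(n * layer$npos, layer$c)
  xhat <- cache$xhat
  grads <- list()
  grads[[paste0(layer$name, ".gamma")]] <- colSums(dY * xhat)
  grads[[paste0(layer$name, ".beta")]] <- colSums(dY)
  m <- nrow(dY)
  if (cache$train) {
    t1 <- dY - rep(colMeans(dY), each = m)
    t2 <- xhat * rep(colMeans(dY * xhat), each = m)
    dX <- (t1 - t2) * rep(g * cache$istd, each = m)
  } else {
    dX <- dY * rep(g * cache$istd, each = m)
  }
  dim(dX) <- c(n, layer$npos * layer$c)
  list(dIn = dX, grads = grads)
}

dense_forward <- function(layer, X, params) {
  W <- params[[paste0(layer$name, ".W")]]
  Y <- X %*% W
  Y <- Y + rep(params[[paste0(layer$name, ".b")]], each = nrow(Y))
  mask <- NULL
  if (layer$relu) { mask <- Y > 0; Y <- Y * mask }
  list(out = Y, cache = list(X = X, mask = mask))
}

dense_backward <- function(layer, cache, dOut, params) {
  if (layer$relu) dOut <- dOut * cache$mask
  W <- params[[paste0(layer$name, ".W")]]
  grads <- list()
  grads[[paste0(layer$name, ".W")]] <- crossprod(cache$X, dOut)
  grads[[paste0(layer$name, ".b")]] <- colSums(dOut)
  list(dIn = dOut %*% t(W), grads = grads)
}

gap_forward <- function(layer, X) {
  n <- nrow(X)
  dim(X) <- c(n * layer$npos, layer$c)
  # mean over positions for each (sample, channel)
  Y <- vapply(seq_len(layer$c), function(cc) {
    M <- X[, cc]
    dim(M) <- c(n, layer$npos)
    rowMeans(M)
  }, numeric(n))
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = n)
  list(out = Y, cache = list(n = n))
}

gap_backward <- function(layer, cache, dOut) {
  n <- cache$n
  dX <- matrix(0, n, layer$npos * layer$c)
  for (cc in seq_len(layer$c))
    dX[, (cc - 1L) * layer$npos + seq_len(layer$npos)] <-
      dOut[, cc] / layer$npos
  list(dIn = dX, grads = list())
}

net_forward <- function(layers, X, params, state, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = conv_forward(l, X, params),
      bn = bn_forward(l, X, params, state, train),
      relu = { m <- X > 0; list(out = X * m, cache = m) },
      dense = dense_forward(l, X, params),
      gap = gap_forward(l, X),
      res = {
        main <- net_forward(l$main, X, params, state, train)
        state <- main$state
        if (!is.null(l$proj)) {
          pr <- net_forward(l$proj, X, params, state, train)
          state <- pr$state
          s <- main$out + pr$out
          pc <- pr$caches
        } else { s <- main$out + X; pc <- NULL }
        m <- s > 0
        list(out = s * m, cache = list(main = main$caches, proj = pc,
                                       mask = m))
      },
      stop("unknown layer type"))
    if (!is.null(r$state)) state <- r$state
    caches[[i]] <- r$cache
    X <- r$out
  }
  list(out = X, caches = caches, state = state)
}

net_backward <- function(layers, caches, dOut, params) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = conv_backward(l, caches[[i]], dOut, params),
      bn = bn_backward(l, caches[[i]], dOut, params),
      relu = list(dIn = dOut * caches[[i]], grads = list()),
      dense = dense_backward(l, caches[[i]], dOut, params),
      gap = gap_backward(l, caches[[i]], dOut),
      res = {
        ca <- caches[[i]]
        dS <- dOut * ca$mask
        rm <- net_backward(l$main, ca$main, dS, params)
        if (!is.null(l$proj)) {
          rp <- net_backward(l$proj, ca$proj, dS, params)
          list(dIn = rm$dIn + rp$dIn, grads = c(rm$grads, rp$grads))
        } else list(dIn = rm$dIn + dS, grads = rm$grads)
      })
    grads <- c(grads, r$grads)
    dOut <- r$dIn
  }
  list(dIn = dOut, grads = grads)
}
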