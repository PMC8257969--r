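# Context-window assembly, the network engine's gradients, training
# behavior on degenerate targets, and prediction flags.

small_dataset <- function(H = 240L, seed = 51L, nDet = 1L) {
  # sparse random features + counts weakly tied to total JID mass
  set.seed(seed)
  jall <- matrix(0, 2500, H)
  present <- runif(H) < 0.7
  for (h in which(present))
    jall[sample(2500, 40), h] <- runif(40)
  jall[, present] <- jall[, present, drop = FALSE] /
    rep(colSums(jall[, present, drop = FALSE]), each = 2500)
  f <- make_features(jall, jall * 0.4)
  cts <- matrix(rpois(H * nDet, 8), nDet, H)
  list(features = f, counts = make_detector_series(cts))
}

test_that("window counts and frame coverage follow the alignment", {
  d <- small_dataset(240L)
  wc <- makeContextWindows(d$features, d$counts, "centered")
  # H hours, centered: the 4 edge hours on each side lack full context
  expect_equal(length(wc@targetHour), 240L - 8L)
  expect_equal(wc@frameHours[1, ], 1:9)
  t0 <- which(wc@targetHour == wc@targetHour[10])
  expect_equal(wc@frameHours[10, ], (wc@targetHour[10] + 1L) + (-4:4))
  wp <- makeContextWindows(d$features, d$counts, "preceding")
  # preceding: strictly causal, no frame at or after the target hour
  expect_true(all(wp@frameHours < matrix(wp@targetHour + 1L,
                                         length(wp@targetHour), 9)))
  # temporal split: every test window later than every training window
  expect_lt(max(wc@targetHour[wc@isTrain]),
            min(wc@targetHour[!wc@isTrain]))
})

test_that("misaligned hour grids are rejected", {
  d <- small_dataset(240L)
  shifted <- make_detector_series(detectorCounts(d$counts), startHour = 5L)
  expect_error(makeContextWindows(d$features, shifted), "hour grids")
})

test_that("z-scored targets reconstruct the counts", {
  d <- small_dataset(240L)
  w <- makeContextWindows(d$features, d$counts, "centered")
  cc <- w@targets[, 1] * w@targetInfo$sd[1] + w@targetInfo$mean[1]
  tcols <- match(w@targetHour, hourIndex(d$counts))
  expect_equal(cc, unname(detectorCounts(d$counts)[1, tcols]))
})

test_that("model output has the mixture shape and valid parameters", {
  d <- small_dataset(192L)
  w <- makeContextWindows(d$features, d$counts, "centered")
  m <- buildModel(2L, "small", seed = 2)
  raw <- jidnet:::forward_windows(m@config, m@params, m@state, w, 1:5)
  expect_equal(dim(raw), c(5L, 2L * 9L))  # 9 mixture values per channel
  mix <- jidnet:::raw_to_mixture(raw[, 1:9], 3L)
  expect_true(all(mix$stds > 0))
  expect_equal(rowSums(mix$weights), rep(1, 5), tolerance = 1e-12)
})

test_that("network gradients match finite differences everywhere", {
  set.seed(42)
  m <- buildModel(2L, "small", seed = 3)
  cfg <- m@config
  Xf <- matrix(runif(18 * 5000) * (runif(18 * 5000) > 0.8), 18, 5000)
  map <- matrix(1:18, 2, 9)
  targets <- matrix(rnorm(4), 2, 2)
  params <- m@params; state <- m@state
  lossfun <- function(params, X = Xf) {
    fwd <- jidnet:::nn_forward(cfg, params, state, X, map, train = FALSE)
    jidnet:::mixture_loss(fwd$raw, targets, 2L, 3L)$loss
  }
  fwd <- jidnet:::nn_forward(cfg, params, state, Xf, map, FALSE)
  ml <- jidnet:::mixture_loss(fwd$raw, targets, 2L, 3L)
  bk <- jidnet:::nn_backward(cfg, params, fwd, ml$dRaw, map, 18,
                             needInputGrad = TRUE)
  eps <- 1e-6
  for (nm in c("c1.W", "c2.W", "c3.W", "c4.W", "b1.gamma", "b3.beta",
               "fc.W", "fc.b", "lstm1.W", "lstm2.U", "lstm3.b",
               "head.W", "head.b")) {
    ii <- sample(length(params[[nm]]), 3)
    num <- vapply(ii, function(i) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- lossfun(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      (l1 - lossfun(p2)) / (2 * eps)
    }, 0)
    expect_lt(max(abs(num - bk$grads[[nm]][ii])), 1e-7)
  }
  ii <- sample(which(Xf != 0), 3)
  num <- vapply(ii, function(i) {
    X2 <- Xf; X2[i] <- X2[i] + eps
    l1 <- lossfun(params, X2)
    X2[i] <- X2[i] - 2 * eps
    (l1 - lossfun(params, X2)) / (2 * eps)
  }, 0)
  expect_lt(max(abs(num - bk$dInput[ii])), 1e-7)
})

test_that("residual-block gradients are correct too", {
  # a miniature bottleneck tower exercising the res/proj/gap paths
  layers <- list(
    jidnet:::make_conv("s", 8L, 8L, 1L, 4L, k = 3L, stride = 1L, pad = 1L),
    jidnet:::make_relu(),
    jidnet:::make_res(
      main = list(
        jidnet:::make_conv("r.a", 8L, 8L, 4L, 2L, k = 1L, stride = 2L,
                           pad = 0L),
        jidnet:::make_relu(),
        jidnet:::make_conv("r.b", 4L, 4L, 2L, 6L, k = 3L, stride = 1L,
                           pad = 1L)),
      proj = list(
        jidnet:::make_conv("r.p", 8L, 8L, 4L, 6L, k = 1L, stride = 2L,
                           pad = 0L))),
    jidnet:::make_gap(16L, 6L),
    jidnet:::make_dense("d", 6L, 3L))
  set.seed(7)
  params <- jidnet:::init_net_params(layers)
  # nudge biases off zero: with zero biases and sparse inputs some
  # pre-activations sit exactly at the ReLU kink, where the analytic
  # subgradient and central differences legitimately disagree
  for (nm in grep("\\.b$", names(params), value = TRUE))
    params[[nm]] <- rnorm(length(params[[nm]]), 0, 0.1)
  state <- jidnet:::init_net_state(layers)
  X <- matrix(rnorm(5 * 64), 5, 64)
  loss <- function(params, X0 = X) {
    out <- jidnet:::net_forward(layers, X0, params, state, FALSE)$out
    sum(out^2)
  }
  fw <- jidnet:::net_forward(layers, X, params, state, FALSE)
  bk <- jidnet:::net_backward(layers, fw$caches, 2 * fw$out, params)
  eps <- 1e-6
  for (nm in names(params)) {
    ii <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    num <- vapply(ii, function(i) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- loss(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      (l1 - loss(p2)) / (2 * eps)
    }, 0)
    expect_lt(max(abs(num - bk$grads[[nm]][ii])), 1e-5)
  }
  num <- (loss(params, X + (X == X[1]) * eps) -
          loss(params, X - (X == X[1]) * eps)) / (2 * eps)
  expect_equal(sum(bk$dIn[X == X[1]]), num, tolerance = 1e-5)
})

test_that("resnet50 extractor builds with a 1024-dim embedding", {
  m <- buildModel(2L, "resnet50", seed = 1)
  e <- jidnet:::net_forward(m@config$layers,
                            matrix(runif(1 * 5000), 1, 5000),
                            m@params, m@state, FALSE)
  expect_equal(ncol(e$out), 1024L)
  expect_true(all(is.finite(e$out)))
})

test_that("training on constant targets predicts that constant", {
  d <- small_dataset(240L, seed = 52L)
  w <- makeContextWindows(d$features, d$counts, "centered")
  w@targets[] <- 0  # constant z-scale target
  m <- buildModel(2L, "small", seed = 4)
  m <- trainModel(m, w, epochs = 4, batchSize = 64, seed = 4)
  # training loss decreases over the first epochs
  expect_lt(m@history$train[4], m@history$train[1])
  raw <- jidnet:::forward_windows(m@config, m@params, m@state, w,
                                  which(!w@isTrain))
  est <- jidnet:::point_estimates_raw(raw, 2L, 3L)
  expect_lt(max(abs(est)), 0.05)
})

test_that("training is deterministic under a fixed seed", {
  d <- small_dataset(192L, seed = 53L)
  w <- makeContextWindows(d$features, d$counts, "centered")
  m0 <- buildModel(2L, "small", seed = 9)
  m1 <- trainModel(m0, w, epochs = 2, batchSize = 64, seed = 6)
  m2 <- trainModel(m0, w, epochs = 2, batchSize = 64, seed = 6)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history, m2@history)
})

test_that("predictSeries flags exactly the all-absent context hours", {
  d <- small_dataset(192L, seed = 54L)
  w <- makeContextWindows(d$features, d$counts, "centered")
  m <- buildModel(2L, "small", seed = 5)
  m <- trainModel(m, w, epochs = 1, batchSize = 64, seed = 5)
  pr <- predictSeries(m, d$features)
  expect_equal(ncol(pr), 192L)
  expect_true(all(is.finite(SummarizedExperiment::assay(pr, "estimate"))))
  pres <- presentHours(d$features)
  expected <- vapply(seq_len(192L), function(t) {
    ctx <- t + (-4:4)
    ctx <- ctx[ctx >= 1 & ctx <= 192]
    !any(pres[ctx])
  }, TRUE)
  expect_equal(SummarizedExperiment::colData(pr)$allAbsent, expected)
})

test_that("channel mismatch between model and windows errors", {
  d <- small_dataset(192L, nDet = 2L)
  w <- makeContextWindows(d$features, d$counts)
  m <- buildModel(2L, "small", seed = 1)  # expects 1 detector
  expect_error(trainModel(m, w, epochs = 1), "channels")
})
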