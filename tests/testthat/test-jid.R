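# Hourly joint interval distribution pipeline: sessionization, the KDE
# grid, and the entropy diagnostic.

test_that("sessionize pairs screen events and counts ITI pairs", {
  log <- make_log(list(
    list(start = 10e3, itis = rep(500, 4), app = "other.app"),   # 5 touches
    list(start = 60e3, itis = rep(800, 2), app = "social.app"))) # 3 touches
  s <- sessionize(log)
  expect_equal(nrow(s), 2L)
  expect_equal(s$nTouches, c(5L, 3L))
  expect_equal(s$category, c("NonSocial", "Social"))
  p <- itiPairs(s)
  # n touches -> n-1 intervals -> n-2 consecutive pairs
  expect_equal(as.integer(table(p$category)["NonSocial"]), 3L)
  expect_equal(as.integer(table(p$category)["Social"]), 1L)
})

test_that("touches outside sessions are discarded", {
  ev <- data.frame(
    timestamp_ms = c(100, 200, 1000, 1500, 2000, 2500, 3000, 4000),
    kind = c("touch", "touch", "screen_on", "touch", "touch", "touch",
             "screen_off", "touch"),
    app_id = c("a", "a", NA, "a", "a", "a", NA, "a"))
  s <- sessionize(TouchLog(ev))
  expect_equal(nrow(s), 1L)
  expect_equal(s$nTouches, 3L)  # pre-session and post-session touches gone
  expect_equal(s$touches[[1]], c(1500, 2000, 2500))
})

test_that("degenerate logs give empty session lists", {
  ev <- data.frame(timestamp_ms = c(1, 2), kind = c("touch", "touch"),
                   app_id = c("a", "a"))
  expect_equal(nrow(sessionize(TouchLog(ev))), 0L)
})

test_that("an unmatched screen_on closes at the last event", {
  ev <- data.frame(timestamp_ms = c(0, 10, 20, 30),
                   kind = c("screen_on", "touch", "touch", "touch"),
                   app_id = c(NA, "a", "a", "a"))
  s <- sessionize(TouchLog(ev))
  expect_equal(nrow(s), 1L)
  expect_equal(s$end, 30)
  expect_equal(s$nTouches, 3L)
})

test_that("the JID axis covers [1.5, 5] with 50 midpoint centers", {
  ax <- jidAxis()
  expect_length(ax, 50L)
  expect_equal(ax[1], 1.535)
  expect_equal(diff(ax)[1], 0.07)
  expect_equal(ax[50], 5 - 0.035)
})

test_that("estimateJID matches a direct KDE evaluation oracle", {
  set.seed(11)
  pairs <- cbind(10^runif(40, 2, 4), 10^runif(40, 2, 4))
  g <- estimateJID(pairs, bandwidth = 0.1)
  # oracle: brute-force Gaussian product kernel at every grid center
  ax <- jidAxis()
  oracle <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50)
    oracle[i, j] <- sum(dnorm(ax[i], log10(pairs[, 1]), 0.1) *
                        dnorm(ax[j], log10(pairs[, 2]), 0.1))
  oracle <- oracle / sum(oracle)
  expect_lt(max(abs(jidValues(g) - oracle)), 1e-9)
  expect_equal(sum(jidValues(g)), 1, tolerance = 1e-12)
})

test_that("concentrated input peaks at the nearest grid cell", {
  g <- estimateJID(cbind(rep(1000, 100), rep(1000, 100)))
  i <- which(jidValues(g) == max(jidValues(g)), arr.ind = TRUE)
  ax <- jidAxis()
  expect_equal(ax[i[1]], ax[which.min(abs(ax - 3))])
  expect_equal(ax[i[2]], ax[which.min(abs(ax - 3))])
  expect_equal(sum(jidValues(g)), 1, tolerance = 1e-12)
})

test_that("swapping pair coordinates transposes the grid", {
  set.seed(3)
  pairs <- cbind(10^runif(30, 2, 3), 10^runif(30, 3, 4))
  g1 <- estimateJID(pairs)
  g2 <- estimateJID(pairs[, 2:1])
  expect_equal(jidValues(g2), t(jidValues(g1)))
})

test_that("the grid is invariant to pair ordering and shifts with scale", {
  set.seed(4)
  pairs <- cbind(10^runif(25, 2.2, 3.2), 10^runif(25, 2.2, 3.2))
  g1 <- estimateJID(pairs)
  g2 <- estimateJID(pairs[sample(25), ])
  expect_equal(jidValues(g1), jidValues(g2), tolerance = 1e-12)
  # doubling every ITI shifts the mode by +log10(2) on both axes
  gd <- estimateJID(pairs * 2)
  i1 <- which(jidValues(g1) == max(jidValues(g1)), arr.ind = TRUE)
  id <- which(jidValues(gd) == max(jidValues(gd)), arr.ind = TRUE)
  ax <- jidAxis()
  expect_lt(abs((ax[id[1]] - ax[i1[1]]) - log10(2)), 0.07)
  expect_lt(abs((ax[id[2]] - ax[i1[2]]) - log10(2)), 0.07)
})

test_that("JID entropy has its closed-form values", {
  expect_equal(jidEntropy(matrix(1 / 2500, 50, 50)), log2(12.25),
               tolerance = 1e-12)
  # concentrated grid is below the uniform maximum
  conc <- jidValues(estimateJID(cbind(rep(1000, 50), rep(1000, 50))))
  expect_lt(jidEntropy(conc), log2(12.25))
  # isotropic Gaussian well inside the support: log2(2*pi*e*sigma^2)
  ax <- jidAxis()
  d <- outer(dnorm(ax, 3.2, 0.3), dnorm(ax, 3.2, 0.3))
  d <- d / sum(d)
  expect_equal(jidEntropy(d), log2(2 * pi * exp(1) * 0.3^2),
               tolerance = 0.05)
  expect_true(is.na(jidEntropy(matrix(0, 50, 50))))
})

test_that("hourly features bookkeeping matches hand counts", {
  h <- 3600e3
  log <- make_log(list(
    list(start = 0.5 * h, itis = rep(400, 5), app = "social.app"),  # 6 touches, hour 0
    list(start = 1.2 * h, itis = rep(300, 3), app = "other.app"),   # 4 touches, hour 1
    list(start = 2.5 * h, itis = 1000, app = "other.app")))         # 2 touches: no pair
  f <- buildHourlyFeatures(log)
  cd <- SummarizedExperiment::colData(f)
  expect_equal(cd$nPairsAll, c(4L, 2L, 0L))
  expect_equal(cd$presentAll, c(TRUE, TRUE, FALSE))
  expect_equal(cd$presentSocial, c(TRUE, FALSE, FALSE))
  # absent hour: all-zero grid
  expect_equal(sum(jidAll(f)[, 3]), 0)
  # present hours sum to 1
  expect_equal(colSums(jidAll(f))[1:2], c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("an all-Social log has identical all and Social grids", {
  h <- 3600e3
  log <- make_log(list(
    list(start = 0.3 * h, itis = rep(350, 6), app = "social.app"),
    list(start = 1.4 * h, itis = rep(700, 4), app = "social.app")))
  f <- buildHourlyFeatures(log)
  pres <- presentHours(f)
  expect_equal(jidSocial(f)[, pres], jidAll(f)[, pres])
})

test_that("Social grids equal the full pipeline run on a filtered log", {
  h <- 3600e3
  sessions <- list(
    list(start = 0.1 * h, itis = rep(300, 8), app = "social.app"),
    list(start = 0.6 * h, itis = rep(450, 5), app = "other.app"),
    list(start = 1.3 * h, itis = rep(250, 7), app = "social.app"))
  full <- buildHourlyFeatures(make_log(sessions), hourRange = c(0L, 1L))
  filt <- buildHourlyFeatures(
    make_log(sessions[c(1, 3)]), hourRange = c(0L, 1L))
  expect_equal(jidSocial(full), jidAll(filt), tolerance = 1e-12)
})

test_that("hour with one touch is absent; empty pairs error", {
  expect_error(estimateJID(matrix(numeric(0), 0, 2)), "no ITI pairs")
  expect_error(estimateJID(cbind(-1, 100)), "positive")
})
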