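# Evaluation statistics: Pearson R with the n-2 dof t-test, BH-FDR,
# daily binning, sparsity, and the performance-vs-activity diagnostic.

test_that("pearsonRTest matches the textbook formula and cor.test", {
  set.seed(61)
  x <- c(2.1, 3.4, 1.2, 5.6, 4.4, 3.3, 2.2, 6.1, 0.5, 4.0)
  y <- c(1.9, 3.1, 2.0, 5.0, 4.9, 2.8, 2.6, 5.5, 1.1, 3.6)
  r <- pearsonRTest(x, y)
  ct <- cor.test(x, y)  # independent cross-check
  expect_equal(r$R, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$t, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(r$p, ct$p.value, tolerance = 1e-12)
  expect_equal(r$dof, unname(ct$parameter))
  # from-scratch formula
  rr <- sum(scale(x, scale = FALSE) * scale(y, scale = FALSE)) /
    sqrt(sum(scale(x, scale = FALSE)^2) * sum(scale(y, scale = FALSE)^2))
  expect_equal(r$R, rr, tolerance = 1e-12)
  expect_equal(r$t, rr * sqrt(8) / sqrt(1 - rr^2), tolerance = 1e-12)
})

test_that("identical series give R = 1 and the dof convention holds", {
  x <- rnorm(791)
  r <- pearsonRTest(x, x)
  expect_equal(r$R, 1)
  # 791 evaluated hours imply a t-statistic on 789 degrees of freedom
  expect_equal(r$dof, 789L)
  expect_lt(r$p, 1e-100)
})

test_that("degenerate inputs are flagged, not fabricated", {
  r <- pearsonRTest(rep(1, 10), rnorm(10))
  expect_true(r$degenerate)
  expect_true(is.na(r$R))
  expect_error(pearsonRTest(1:2, 1:2), "at least 3")
})

test_that("bhFDR matches an exhaustive step-up oracle", {
  oracle <- function(p, alpha) {
    m <- length(p)
    ord <- order(p)
    k <- 0
    for (i in seq_len(m)) if (p[ord[i]] <= alpha * i / m) k <- i
    rej <- rep(FALSE, m)
    if (k > 0) rej[ord[seq_len(k)]] <- TRUE
    rej
  }
  set.seed(62)
  for (i in 1:50) {
    m <- sample(1:10, 1)
    p <- round(runif(m)^2, 3)
    got <- bhFDR(p, 0.05)
    expect_equal(got$rejected, oracle(p, 0.05))
    expect_equal(got$adjusted, p.adjust(p, "BH"))
    # rejection iff adjusted p below the threshold
    expect_equal(got$rejected, got$adjusted <= 0.05)
  }
})

test_that("bhFDR handles edge families", {
  expect_true(bhFDR(0.01, 0.05)$rejected)
  r <- bhFDR(rep(1, 5), 0.05)
  expect_false(any(r$rejected))
  expect_equal(r$adjusted, rep(1, 5))
  expect_error(bhFDR(c(0.2, 1.3)), "0, 1")
})

test_that("daily binning sums days and is shuffle-invariant within days", {
  set.seed(63)
  H <- 24 * 12
  hours <- 0:(H - 1)
  obs <- rpois(H, 10)
  r0 <- dailyBinnedCorrelation(obs, obs, hours)
  expect_equal(r0$R, 1)
  expect_equal(r0$nDays, 12L)
  # shuffling predictions within each day leaves daily sums unchanged
  pred <- rnorm(H, obs, 2)
  shuf <- unlist(lapply(split(pred, hours %/% 24), sample),
                 use.names = FALSE)
  r1 <- dailyBinnedCorrelation(pred, obs, hours)
  r2 <- dailyBinnedCorrelation(shuf, obs, hours)
  expect_equal(r1$R, r2$R, tolerance = 1e-12)
})

test_that("daily binning drops partially masked days entirely", {
  H <- 24 * 10
  hours <- 0:(H - 1)
  x <- rnorm(H)
  mask <- rep(TRUE, H)
  mask[30] <- FALSE  # one masked hour in day 2
  r <- dailyBinnedCorrelation(x, x, hours, mask)
  expect_equal(r$nDays, 9L)
  expect_error(dailyBinnedCorrelation(x[1:72], x[1:72], hours[1:72]),
               "5 complete days")
})

test_that("multi-day coupling survives daily binning, diurnal does not", {
  set.seed(64)
  H <- 24 * 40
  hours <- 0:(H - 1)
  # shared slow (5-day) modulation: daily sums stay correlated
  slow <- sin(2 * pi * hours / (24 * 5))
  obs1 <- rpois(H, exp(2 + 0.5 * slow))
  pred1 <- exp(2 + 0.5 * slow) + rnorm(H, 0, 0.5)
  r1 <- dailyBinnedCorrelation(pred1, obs1, hours)
  expect_gt(r1$R, 0.5)
  expect_lt(r1$p, 0.01)
  # shared 24 h cycle only: daily sums are flat, R_daily ~ 0
  diurnal <- sin(2 * pi * hours / 24)
  obs2 <- rpois(H, exp(2 + 0.5 * diurnal))
  pred2 <- exp(2 + 0.5 * diurnal) + rnorm(H, 0, 0.5)
  r2 <- dailyBinnedCorrelation(pred2, obs2, hours)
  expect_lt(abs(r2$R), 0.35)
})

test_that("sparsity is the zero-hour fraction per detector", {
  cts <- rbind(rep(0, 100), rep(2, 100), c(rep(0, 25), rep(3, 75)))
  s <- make_detector_series(cts)
  sp <- detectorSparsity(s)
  expect_equal(unname(sp), c(1, 0, 0.25))
  # NA device-gap hours are excluded from the denominator
  cts2 <- matrix(c(rep(NA_real_, 50), rep(0, 25), rep(1, 25)), 1)
  expect_equal(unname(detectorSparsity(make_detector_series(cts2))), 0.5)
})

test_that("performance-activity correlation detects the relationship", {
  set.seed(65)
  sparsity <- seq(0.1, 0.9, length.out = 8)
  perf <- data.frame(R = 0.6 - 0.5 * sparsity + rnorm(8, 0, 0.02),
                     sparsity = sparsity,
                     entropy = rep(3, 8))
  out <- performanceVsActivity(perf)
  expect_lt(out$sparsity$R, -0.9)
  expect_equal(out$sparsity$dof, 6L)  # n - 2, shared convention
  expect_true(out$entropy$degenerate)  # constant entropy flagged
  expect_error(performanceVsActivity(perf[1:3, ]), "at least 4")
})
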