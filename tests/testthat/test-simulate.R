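# The paired synthetic generator: determinism, configured moments,
# gaps, and planted structure.

test_that("config validation catches bad inputs", {
  expect_error(simulationConfig(itiMixture = data.frame(
    mean = 2.5, sd = 0.3, weight = 0.7)), "sum to 1")
  expect_error(simulationConfig(sessionRatePerHour = rep(-1, 24)),
               "nonnegative")
  expect_error(simulationConfig(nDetectors = 5), "1..4")
  expect_error(simulationConfig(baselineRate = 0), "positive")
  expect_error(simulationConfig(socialFraction = 1.2), "0,1")
})

test_that("a zero session rate produces an empty log", {
  cfg <- simulationConfig(durationDays = 2,
                          sessionRatePerHour = rep(0, 24), seed = 3)
  expect_equal(nrow(touchEvents(simulateTouchLog(cfg))), 0L)
})

test_that("the generator is bit-deterministic under a fixed seed", {
  cfg <- simulationConfig(durationDays = 3, seed = 17)
  l1 <- simulateTouchLog(cfg)
  l2 <- simulateTouchLog(cfg)
  expect_identical(touchEvents(l1), touchEvents(l2))
  l3 <- simulateTouchLog(simulationConfig(durationDays = 3, seed = 18))
  expect_false(identical(touchEvents(l1), touchEvents(l3)))
})

test_that("a single-component mixture reproduces its median ITI", {
  cfg <- simulationConfig(
    durationDays = 10,
    itiMixture = data.frame(mean = 2.5, sd = 0.3, weight = 1),
    seed = 5)
  log <- simulateTouchLog(cfg)
  iti <- unlist(lapply(sessionize(log)$touches, diff), use.names = FALSE)
  expect_gt(length(iti), 5000)
  # numeric oracle: the median of the lognormal component is 10^2.5 ms
  expect_equal(median(iti), 10^2.5, tolerance = 0.05)
})

test_that("all touches fall inside screen-on/off sessions", {
  cfg <- simulationConfig(durationDays = 2, seed = 9)
  log <- simulateTouchLog(cfg)
  ev <- touchEvents(log)
  s <- sessionize(log)
  expect_equal(sum(s$nTouches), sum(ev$kind == "touch"))
  expect_true(all(unlist(s$touches) >= rep(s$start, s$nTouches)))
  expect_true(all(unlist(s$touches) <= rep(s$end, s$nTouches)))
})

test_that("gap hours carry no touches while counts continue", {
  gaps <- list(c(24, 48), c(60, 66))
  cfg <- simulationConfig(durationDays = 4, gapSchedule = gaps, seed = 21)
  ds <- makePairedDataset(cfg)
  hrs <- floor(touchEvents(ds$log)$timestamp_ms[
    touchEvents(ds$log)$kind == "touch"] / 3600e3)
  expect_false(any(hrs >= 24 & hrs < 48))
  expect_false(any(hrs >= 60 & hrs < 66))
  expect_false(anyNA(detectorCounts(ds$counts)[, 25:48]))
  # flanking hours still have activity
  expect_gt(sum(hrs < 24), 0)
})

test_that("mean counts match the latent rate within Monte-Carlo error", {
  cfg <- simulationConfig(durationDays = 45, seed = 33)
  ds <- makePairedDataset(cfg)
  cts <- detectorCounts(ds$counts)[1, ]
  rate <- ds$truth$hourlyRate[1, ]
  se <- sqrt(mean(rate) / length(cts))  # Poisson oracle
  expect_lt(abs(mean(cts) - mean(rate)), 3 * se)
})

test_that("zero coupling leaves counts independent of the summary", {
  # counts with no planted cycle and no coupling: raw correlation with
  # the behavioral summary is sampling noise over >= 1000 hours
  cfg <- simulationConfig(durationDays = 45, couplingStrength = 0,
                          diurnalAmplitude = 0, seed = 41)
  ds <- makePairedDataset(cfg)
  r <- cor(detectorCounts(ds$counts)[1, ], ds$truth$couplingSeries)
  expect_lt(abs(r), 0.1)
  # with a diurnal rate cycle both series share the clock, so the raw
  # correlation is real and substantial even without coupling; removing
  # hour-of-day structure from both restores independence
  cfg2 <- simulationConfig(durationDays = 45, couplingStrength = 0,
                           seed = 41)
  ds2 <- makePairedDataset(cfg2)
  d <- polynomialDetrend(ds2$counts)
  zr <- resid(lm(ds2$truth$couplingSeries ~
                   factor(hourIndex(ds2$counts) %% 24)))
  expect_lt(abs(cor(detrendResidual(d)[1, ], zr)), 0.1)
})

test_that("planted diurnal and multidien cycles are recoverable", {
  cfg <- simulationConfig(durationDays = 45, diurnalAmplitude = 0.5,
                          seed = 55)
  ds <- makePairedDataset(cfg)
  p <- waveletPeriodogram(detectorCounts(ds$counts)[1, ],
                          periods = 2 * 2^seq(0, 7, 1 / 24))
  expect_gte(peakPeriod(p), 22)
  expect_lte(peakPeriod(p), 26)

  cfg2 <- simulationConfig(durationDays = 120, multidienPeriodDays = 21,
                           multidienAmplitude = 0.5, seed = 56)
  ds2 <- makePairedDataset(cfg2)
  # focus on the multidien band; 1000+ hour series
  pg <- bootstrapPeriodogram(
    detectorCounts(ds2$counts)[1, ],
    periods = 24 * 14 * 2^seq(0, 1, 1 / 24),  # 14 to 28 days
    nShuffles = 200, level = 95, seed = 1)
  tab <- periodogramTable(pg)
  peak <- tab$period[which.max(tab$power)]
  expect_gt(peak / 24, 17)
  expect_lt(peak / 24, 25)
  expect_true(tab$significant[which.max(tab$power)])
})

test_that("social sessions appear at the configured fraction", {
  cfg <- simulationConfig(durationDays = 8, socialFraction = 0.4,
                          seed = 60)
  s <- sessionize(simulateTouchLog(cfg))
  frac <- mean(s$category == "Social")
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / nrow(s)))
})

test_that("detector counts are reproducible and respect nDetectors", {
  cfg <- simulationConfig(durationDays = 8, nDetectors = 3L, seed = 70)
  ds1 <- makePairedDataset(cfg)
  ds2 <- makePairedDataset(cfg)
  expect_identical(detectorCounts(ds1$counts), detectorCounts(ds2$counts))
  expect_equal(nrow(ds1$counts), 3L)
  # scaled baselines: later detectors fire less
  m <- rowMeans(detectorCounts(ds1$counts))
  expect_true(all(diff(m) < 0))
})
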