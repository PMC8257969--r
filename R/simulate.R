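#' Configuration for the paired synthetic generator
#'
#' Describes a simulated subject: smartphone usage as an inhomogeneous
#' Poisson session process over clock hours with geometric session lengths
#' and log10-normal mixture inter-touch intervals (15 ms timestamp jitter,
#' matching the logging accuracy of the background recording app), and an
#' implanted detector emitting hourly Poisson counts whose latent rate
#' carries a diurnal cycle, an optional multidien cycle, and a
#' configurable log-linear coupling to a summary of the subject's own
#' hourly JID.
#'
#' @param durationDays simulated span in days.
#' @param sessionRatePerHour 24 nonnegative values: expected usage
#'   sessions per hour by hour of day.
#' @param tapsPerSessionMean mean touches per session (geometric, >= 1).
#' @param itiMixture data.frame with columns \code{mean}, \code{sd}
#'   (log10 ms) and \code{weight} (summing to 1): the ITI mixture.
#' @param socialFraction probability a session is on a Social-category app.
#' @param jitterSdMs standard deviation of Gaussian timestamp jitter (ms).
#' @param nDetectors number of detector-channel pairs (1-4).
#' @param baselineRate baseline detection counts/hour (> 0).
#' @param diurnalAmplitude relative amplitude of the 24-h rate cycle in
#'   [0, 1].
#' @param multidienPeriodDays optional period of a planted multi-day rate
#'   cycle.
#' @param multidienAmplitude relative amplitude of the multidien cycle.
#' @param couplingStrength coefficient on the standardized behavioral
#'   summary in the log rate (0 = no behavior-count coupling).
#' @param couplingFeature name of the coupled JID summary: currently
#'   \code{"fastITI"}, the probability mass of the sub-region with both
#'   log10-ITI axes below 2.5 (intervals faster than ~316 ms).
#' @param gapSchedule list of length-2 vectors \code{c(startHour,
#'   endHour)}: half-open intervals (hours since simulation start) with no
#'   behavioral recording; detector counts continue through gaps.
#' @param seed integer RNG seed; identical seed and config give
#'   bit-identical output.
#' @return a validated configuration list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(durationDays = 180L,
                             sessionRatePerHour = c(rep(0.25, 6), 1, 2,
                               rep(3, 13), 2.5, 2, 1),
                             tapsPerSessionMean = 40,
                             itiMixture = data.frame(
                               mean = c(2.4, 3.1, 4.0),
                               sd = c(0.25, 0.30, 0.35),
                               weight = c(0.50, 0.35, 0.15)),
                             socialFraction = 0.4,
                             jitterSdMs = 15,
                             nDetectors = 1L,
                             baselineRate = 10,
                             diurnalAmplitude = 0.5,
                             multidienPeriodDays = NULL,
                             multidienAmplitude = 0.3,
                             couplingStrength = 0,
                             couplingFeature = "fastITI",
                             gapSchedule = list(),
                             seed = 1L) {
  cfg <- list(durationDays = as.integer(durationDays),
              sessionRatePerHour = sessionRatePerHour,
              tapsPerSessionMean = tapsPerSessionMean,
              itiMixture = itiMixture, socialFraction = socialFraction,
              jitterSdMs = jitterSdMs, nDetectors = as.integer(nDetectors),
              baselineRate = baselineRate,
              diurnalAmplitude = diurnalAmplitude,
              multidienPeriodDays = multidienPeriodDays,
              multidienAmplitude = multidienAmplitude,
              couplingStrength = couplingStrength,
              couplingFeature = couplingFeature,
              gapSchedule = gapSchedule, seed = as.integer(seed))
  if (cfg$durationDays < 1) stop("durationDays must be >= 1")
  if (length(cfg$sessionRatePerHour) != 24 || any(cfg$sessionRatePerHour < 0))
    stop("sessionRatePerHour must be 24 nonnegative values")
  if (cfg$tapsPerSessionMean < 1) stop("tapsPerSessionMean must be >= 1")
  mx <- cfg$itiMixture
  if (!all(c("mean", "sd", "weight") %in% names(mx)))
    stop("itiMixture needs columns mean, sd, weight")
  if (abs(sum(mx$weight) - 1) > 1e-8 || any(mx$weight < 0))
    stop("itiMixture weights must be nonnegative and sum to 1")
  if (any(mx$sd <= 0)) stop("itiMixture sds must be positive")
  if (cfg$socialFraction < 0 || cfg$socialFraction > 1)
    stop("socialFraction must be in [0,1]")
  if (cfg$jitterSdMs < 0) stop("jitterSdMs must be nonnegative")
  if (cfg$nDetectors < 1 || cfg$nDetectors > 4)
    stop("nDetectors must be in 1..4")
  if (cfg$baselineRate <= 0) stop("baselineRate must be positive")
  if (cfg$diurnalAmplitude < 0 || cfg$diurnalAmplitude > 1)
    stop("diurnalAmplitude must be in [0,1]")
  if (!is.null(cfg$multidienPeriodDays) && cfg$multidienPeriodDays <= 0)
    stop("multidienPeriodDays must be positive")
  if (!cfg$couplingFeature %in% c("fastITI"))
    stop("unknown couplingFeature")
  class(cfg) <- "SimulationConfig"
  cfg
}

in_gap <- function(hours, gapSchedule) {
  if (!length(gapSchedule)) return(rep(FALSE, length(hours)))
  out <- rep(FALSE, length(hours))
  for (g in gapSchedule) out <- out | (hours >= g[1] & hours < g[2])
  out
}

#' Simulate a smartphone touch log
#'
#' Sessions arise from an inhomogeneous Poisson process over clock hours
#' with the configured hour-of-day intensity; each session has a geometric
#' number of touches with ITIs drawn from the configured log10-normal
#' mixture, timestamps jittered with the configured standard deviation and
#' re-sorted. Sessions are bounded by screen-on/screen-off events, carry a
#' single app (Social with probability \code{socialFraction}), never
#' overlap, and produce no touches inside gap-schedule hours.
#'
#' @param config a [simulationConfig()].
#' @return a [TouchLog-class].
#' @export
simulateTouchLog <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  H <- config$durationDays * 24L
  mx <- config$itiMixture
  chunks <- vector("list", 4096L); nCh <- 0L
  prevEnd <- -Inf
  for (h in seq_len(H) - 1L) {
    lam <- config$sessionRatePerHour[h %% 24L + 1L]
    nS <- if (lam > 0) stats::rpois(1L, lam) else 0L
    if (!nS) next
    if (in_gap(h, config$gapSchedule)) next
    starts <- sort(stats::runif(nS, h, h + 1)) * MS_PER_HOUR
    for (s0 in starts) {
      nTap <- 1L + stats::rgeom(1L, 1 / config$tapsPerSessionMean)
      comp <- sample.int(nrow(mx), nTap - 1L, replace = TRUE,
                         prob = mx$weight)
      iti <- if (nTap > 1L)
        10^stats::rnorm(nTap - 1L, mx$mean[comp], mx$sd[comp]) else numeric(0)
      tt <- s0 + cumsum(c(0, iti))
      tt <- sort(tt + stats::rnorm(nTap, 0, config$jitterSdMs))
      tt <- tt[!in_gap(floor(tt / MS_PER_HOUR), config$gapSchedule)]
      if (!length(tt)) next
      on <- max(tt[1] - 200, prevEnd + 1)
      if (on > tt[1]) next  # squeezed out by the previous session
      off <- tt[length(tt)] + 200
      app <- if (stats::runif(1) < config$socialFraction)
        "com.sim.social" else "com.sim.other"
      nCh <- nCh + 1L
      if (nCh > length(chunks)) chunks <- c(chunks, vector("list", nCh))
      chunks[[nCh]] <- list(t = c(on, tt, off), app = app, n = length(tt))
      prevEnd <- off
    }
  }
  chunks <- chunks[seq_len(nCh)]
  if (!nCh)
    return(TouchLog(data.frame(timestamp_ms = numeric(),
                               kind = character(), app_id = character()),
                    c(com.sim.social = "Social",
                      com.sim.other = "NonSocial")))
  ev <- data.frame(
    timestamp_ms = unlist(lapply(chunks, `[[`, "t"), use.names = FALSE),
    kind = unlist(lapply(chunks, function(s)
      c("screen_on", rep("touch", s$n), "screen_off")), use.names = FALSE),
    app_id = unlist(lapply(chunks, function(s)
      c(NA, rep(s$app, s$n), NA)), use.names = FALSE))
  ev <- ev[order(ev$timestamp_ms), , drop = FALSE]
  TouchLog(ev, c(com.sim.social = "Social", com.sim.other = "NonSocial"))
}

#' Hourly value of a named JID coupling summary
#'
#' \code{"fastITI"} is the integral of the all-ITI JID over the sub-region
#' where both axes are below 2.5 log10 ms; absent hours contribute 0.
#'
#' @param features an [HourlyFeatures-class].
#' @param feature summary name.
#' @return numeric vector, one value per hour.
#' @export
couplingFeatureSeries <- function(features, feature = "fastITI") {
  region <- couplingFeatureRegion(feature)
  as.numeric(crossprod(as.numeric(region), jidAll(features)))
}

#' @rdname couplingFeatureSeries
#' @return \code{couplingFeatureRegion}: the 50x50 logical region mask.
#' @export
couplingFeatureRegion <- function(feature = "fastITI") {
  ax <- jidAxis()
  switch(feature,
    fastITI = outer(ax < 2.5, ax < 2.5, `&`),
    stop("unknown couplingFeature"))
}

#' Simulate hourly detector counts coupled to behavior
#'
#' Counts are Poisson with latent rate
#' \code{baseline * diurnal(hourOfDay) * multidien(hour) *
#' exp(couplingStrength * z(hour))}, where \code{z} is the standardized
#' hourly coupling summary computed from the touch log through the same
#' JID pipeline used downstream, winsorized at +/- 3 standard deviations
#' so that sparse-hour estimation noise cannot produce unbounded rates. Counts are generated for every hour,
#' including behavioral gaps (the implanted device records independently
#' of phone use). When several detector-channel pairs are simulated their
#' baselines are scaled (1, 0.7, 0.5, 0.35) and draws are independent.
#'
#' @param log a [TouchLog-class] covering the configured span.
#' @param config the [simulationConfig()] used to generate \code{log}.
#' @param features optional precomputed [HourlyFeatures-class] for
#'   \code{log} (computed if missing).
#' @return list with elements \code{counts} (a [DetectorSeries-class]) and
#'   \code{truth} (latent \code{hourlyRate} matrix, standardized
#'   \code{couplingSeries}, planted \code{cycleComponents}, and the
#'   \code{features} used).
#' @export
simulateDetectorCounts <- function(log, config, features = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  H <- config$durationDays * 24L
  if (is.null(features))
    features <- buildHourlyFeatures(log, hourRange = c(0L, H - 1L))
  if (ncol(features) != H) stop("log and config disagree on the time span")
  set.seed(config$seed + 1L)
  f <- couplingFeatureSeries(features, config$couplingFeature)
  z <- if (stats::sd(f) > 0) (f - mean(f)) / stats::sd(f) else f * 0
  # winsorize: single sparse hours can carry nearly all KDE mass in the
  # coupled sub-region, and an unbounded log-linear link would turn such
  # outliers into physiologically absurd rate excursions
  z <- pmin(pmax(z, -3), 3)
  hod <- (seq_len(H) - 1L) %% 24L
  diurnal <- 1 + config$diurnalAmplitude * cos(2 * pi * (hod - 18) / 24)
  multi <- rep(1, H)
  cyc <- list(diurnal = c(period = 24, amplitude = config$diurnalAmplitude))
  if (!is.null(config$multidienPeriodDays)) {
    P <- config$multidienPeriodDays * 24
    multi <- 1 + config$multidienAmplitude * sin(2 * pi * (seq_len(H) - 1) / P)
    cyc$multidien <- c(period = P, amplitude = config$multidienAmplitude)
  }
  base <- config$baselineRate * c(1, 0.7, 0.5, 0.35)[seq_len(config$nDetectors)]
  rate <- outer(base, diurnal * multi * exp(config$couplingStrength * z))
  cts <- matrix(stats::rpois(length(rate), rate), nrow(rate))
  labs <- paste0("L", rep(1:2, each = 2), "D",
                 rep(1:2, 2))[seq_len(config$nDetectors)]
  rownames(cts) <- labs
  se <- SummarizedExperiment(
    assays = list(counts = cts),
    rowData = DataFrame(detectorLabel = labs),
    colData = DataFrame(hourIndex = seq_len(H) - 1L))
  list(counts = new("DetectorSeries", se),
       truth = list(hourlyRate = rate, couplingSeries = z,
                    cycleComponents = cyc, features = features))
}

#' Generate a complete paired synthetic dataset
#'
#' Convenience composition of [simulateTouchLog()],
#' [buildHourlyFeatures()] and [simulateDetectorCounts()] under one seed.
#'
#' @param config a [simulationConfig()].
#' @return list: \code{log}, \code{features}, \code{counts}, \code{truth}.
#' @export
makePairedDataset <- function(config) {
  log <- simulateTouchLog(config)
  H <- config$durationDays * 24L
  features <- buildHourlyFeatures(log, hourRange = c(0L, H - 1L))
  sim <- simulateDetectorCounts(log, config, features)
  list(log = log, features = features, counts = sim$counts,
       truth = sim$truth)
}
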