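# Complex Morlet continuous wavelet transform (center frequency 6),
# Torrence & Compo conventions: scale <-> period via the Morlet Fourier
# factor, FFT-based transform with zero padding to the next power of two.

MORLET_W0 <- 6
MORLET_FOURIER <- 4 * pi / (MORLET_W0 + sqrt(2 + MORLET_W0^2))  # period = s * this
MORLET_CDELTA <- 0.776
MORLET_PSI0 <- pi^(-1 / 4)

period_to_scale <- function(period) period / MORLET_FOURIER

# Fourier transform of the (normalised) Morlet daughter at one scale,
# evaluated on the angular frequency grid of an npad-point FFT.
morlet_hat <- function(scale, npad, dt = 1) {
  k <- c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1))
  w <- 2 * pi * k / (npad * dt)
  out <- numeric(npad)
  pos <- w > 0
  out[pos] <- sqrt(2 * pi * scale / dt) * MORLET_PSI0 *
    exp(-(scale * w[pos] - MORLET_W0)^2 / 2)
  out
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# CWT of the columns of X (each a length-N series, zero-mean recommended).
# Returns, for one scale, the npad x m complex coefficient matrix truncated
# to the first N rows.
cwt_one_scale <- function(Xhat, scale, N, dt = 1) {
  npad <- nrow(Xhat)
  W <- stats::mvfft(Xhat * morlet_hat(scale, npad, dt), inverse = TRUE) / npad
  W[seq_len(N), , drop = FALSE]
}

# Indices retained when averaging at a scale: outside the cone of influence
# (e-folding time sqrt(2)*s from each edge), but always keeping at least the
# central quarter of the series so that scales near the precondition limit
# remain measurable.
coi_keep <- function(N, scale) {
  drop <- min(ceiling(sqrt(2) * scale), floor(3 * N / 8))
  seq.int(drop + 1L, N - drop)
}

default_periods <- function(N, minPeriod = 2, maxPeriod = NULL,
                            voicesPerOctave = 24) {
  lim <- min(35 * 24, N / 2)
  if (!is.null(maxPeriod)) lim <- min(lim, maxPeriod)
  if (lim < minPeriod) stop("series too short for the minimum period")
  minPeriod * 2^seq(0, log2(lim / minPeriod), by = 1 / voicesPerOctave)
}

check_periods <- function(series, periods) {
  N <- length(series)
  if (max(periods) > N / 2)
    stop(sprintf(
      "series of %d hours supports periods up to %.1f h (requested %.1f h)",
      N, N / 2, max(periods)))
}

prep_series <- function(series) {
  if (anyNA(series)) series[is.na(series)] <- mean(series, na.rm = TRUE)
  series - mean(series)
}

# power per scale for the columns of X (N x m, already demeaned):
# sqrt(mean_t |W|) with the cone of influence excluded.
power_matrix <- function(X, periods, chunk = 256L) {
  N <- nrow(X); m <- ncol(X)
  npad <- next_pow2(N)
  Xp <- rbind(X, matrix(0, npad - N, m))
  P <- matrix(0, length(periods), m)
  for (j0 in seq(1L, m, by = chunk)) {
    jj <- j0:min(m, j0 + chunk - 1L)
    Xhat <- stats::mvfft(Xp[, jj, drop = FALSE])
    for (i in seq_along(periods)) {
      s <- period_to_scale(periods[i])
      W <- cwt_one_scale(Xhat, s, N)
      keep <- coi_keep(N, s)
      P[i, jj] <- sqrt(colMeans(Mod(W[keep, , drop = FALSE])))
    }
  }
  P
}

#' Wavelet periodogram of an hourly series
#'
#' Computes the complex Morlet (center frequency 6) continuous wavelet
#' transform of an hourly series and summarises it as a periodogram:
#' power at each scale is the square root of the time average of the
#' transform modulus, with edge effects excluded via the cone of
#' influence. Periods are logarithmically spaced (24 voices per octave)
#' from 2 h up to half the series length (capped at 35 days) unless given
#' explicitly.
#'
#' @param series numeric hourly series (a vector); NAs are replaced by the
#'   series mean before transforming.
#' @param periods optional increasing vector of periods in hours; the
#'   largest must not exceed half the series length.
#' @return a [Periodogram-class] (no bootstrap attached).
#' @examples
#' x <- sin(2 * pi * (1:1440) / 24)
#' peakPeriod(waveletPeriodogram(x))  # ~24
#' @export
waveletPeriodogram <- function(series, periods = NULL) {
  series <- as.numeric(series)
  if (is.null(periods)) periods <- default_periods(length(series))
  check_periods(series, periods)
  x <- prep_series(series)
  p <- power_matrix(matrix(x, ncol = 1), periods)[, 1]
  new("Periodogram", periods = periods, power = p,
      ciUpper = rep(NA_real_, length(periods)),
      significant = rep(FALSE, length(periods)),
      level = NA_real_, nShuffles = 0L)
}

#' Shuffle-bootstrap significance for a wavelet periodogram
#'
#' Builds the null distribution of periodogram power at each scale by
#' uniformly permuting the series \code{nShuffles} times (destroying all
#' temporal structure while preserving the marginal distribution) and
#' taking the per-scale upper \code{level}\% quantile as the significance
#' threshold. A period is flagged significant when the observed power
#' exceeds its threshold.
#'
#' @inheritParams waveletPeriodogram
#' @param nShuffles number of permutations (>= 100).
#' @param level confidence level in percent (e.g. 95 or 99.9).
#' @param seed optional integer seed for reproducible permutations.
#' @return a [Periodogram-class] with \code{ciUpper} and
#'   \code{significant} filled in.
#' @export
bootstrapPeriodogram <- function(series, periods = NULL, nShuffles = 1000L,
                                 level = 95, seed = NULL) {
  if (nShuffles < 100L) stop("at least 100 shuffles are required")
  series <- as.numeric(series)
  if (is.null(periods)) periods <- default_periods(length(series))
  check_periods(series, periods)
  if (!is.null(seed)) set.seed(seed)
  x <- prep_series(series)
  N <- length(x)
  obs <- power_matrix(matrix(x, ncol = 1), periods)[, 1]
  Xs <- vapply(seq_len(nShuffles), function(i) x[sample.int(N)], numeric(N))
  Pnull <- power_matrix(Xs, periods)
  ci <- apply(Pnull, 1, stats::quantile, probs = level / 100, names = FALSE)
  new("Periodogram", periods = periods, power = obs, ciUpper = ci,
      significant = obs > ci, level = level, nShuffles = as.integer(nShuffles))
}

# 4-connected component labels of a logical matrix (0 = background)
label_components <- function(sig) {
  nr <- nrow(sig); nc <- ncol(sig)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(sig & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !sig[p]) next
      lab[p] <- cur
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      if (i > 1L)  stack <- c(stack, p - 1L)
      if (i < nr)  stack <- c(stack, p + 1L)
      if (j > 1L)  stack <- c(stack, p - nr)
      if (j < nc)  stack <- c(stack, p + nr)
    }
  }
  lab
}

# TRUE for components containing at least one all-significant 2x2 square
mask_small_clusters <- function(sig) {
  nr <- nrow(sig); nc <- ncol(sig)
  lab <- label_components(sig)
  sq <- sig[-nr, -nc] & sig[-1, -nc] & sig[-nr, -1] & sig[-1, -1]
  keep <- unique(lab[-nr, -nc][sq])  # top-left corners of 2x2 squares
  keep <- keep[keep != 0L]
  lab %in% keep & sig
}

#' Per-pixel cycle power map over the JID grid
#'
#' For each of the 2500 JID pixel time series (absent hours stored as
#' zeros), computes wavelet power at a single period (typically 24 h) and
#' tests it against \code{nShuffles} independent permutations of that
#' pixel's series. Significant 4-connected clusters that do not contain a
#' fully significant 2x2 pixel square are masked out.
#'
#' @param features an [HourlyFeatures-class] series (>= 2x the requested
#'   period in hours; >= 14 days is recommended for a 24 h map).
#' @param period analysed period in hours (default 24).
#' @param nShuffles permutations per pixel (default 100).
#' @param level confidence level in percent.
#' @param space \code{"all"} or \code{"social"} feature space.
#' @param seed optional integer seed.
#' @return a [CyclePowerMap-class].
#' @export
pixelwiseCycleMap <- function(features, period = 24, nShuffles = 100L,
                              level = 95, space = c("all", "social"),
                              seed = NULL) {
  space <- match.arg(space)
  M <- if (space == "all") jidAll(features) else jidSocial(features)
  N <- ncol(M)
  check_periods(numeric(N), period)
  if (!is.null(seed)) set.seed(seed)
  s <- period_to_scale(period)
  npad <- next_pow2(N)
  keep <- coi_keep(N, s)
  mh <- morlet_hat(s, npad)
  pow <- matrix(0, 50, 50)
  sig <- matrix(FALSE, 50, 50)
  q <- level / 100
  for (px in seq_len(2500L)) {
    x <- M[px, ]
    if (all(x == x[1])) next  # constant pixel: no cycle, not significant
    x <- x - mean(x)
    Xs <- vapply(seq_len(nShuffles), function(i) x[sample.int(N)], numeric(N))
    Xp <- rbind(cbind(x, Xs), matrix(0, npad - N, nShuffles + 1L))
    W <- stats::mvfft(stats::mvfft(Xp) * mh, inverse = TRUE) / npad
    pw <- sqrt(colMeans(Mod(W[keep, , drop = FALSE])))
    pow[px] <- pw[1]
    sig[px] <- pw[1] > stats::quantile(pw[-1], probs = q, names = FALSE)
  }
  new("CyclePowerMap", period = period, power = pow, significant = sig,
      mask = mask_small_clusters(sig), level = level,
      nShuffles = as.integer(nShuffles))
}
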