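new_detrended <- function(series, fitted, residual, method, extra = list()) {
  se <- as(series, "SummarizedExperiment")
  assays(se) <- c(assays(se), list(fitted = fitted, residual = residual))
  md <- metadata(se)
  md$method <- method
  md[names(extra)] <- extra
  metadata(se) <- md
  new("DetrendedSeries", se)
}

hour_of_day <- function(series) colData(series)$hourIndex %% 24L

fit_hod_poly <- function(y, hod, degree, fitIdx) {
  # orthogonal polynomial in hour-of-day, least squares over the fit hours
  df <- data.frame(y = y, hod = hod)
  fit <- stats::lm(y ~ poly(hod, degree, raw = TRUE),
                   data = df[fitIdx, , drop = FALSE])
  unname(stats::predict(fit, newdata = df))
}

#' Remove the 24-h cycle by an hour-of-day polynomial fit
#'
#' Fits, per detector channel, a degree-\code{degree} polynomial in hour
#' of day (0-23, least squares pooling all days) and subtracts the fitted
#' daily profile from the counts. Only the folded 24-h profile is
#' modelled, so all other frequencies are preserved. The fit is not
#' constrained to be cyclic at the 23-to-0 boundary; the resulting
#' discontinuity is a documented property of the method.
#'
#' @param series a [DetectorSeries-class] with >= 7 days of data.
#' @param degree polynomial degree (default 5).
#' @param fitHours optional logical vector over hours selecting the hours
#'   used to estimate the profile (e.g. a training split, to avoid
#'   leakage); the profile is always subtracted from all hours.
#' @return a [DetrendedSeries-class]; \code{counts == fitted + residual}
#'   exactly.
#' @export
polynomialDetrend <- function(series, degree = 5L, fitHours = NULL) {
  cts <- detectorCounts(series)
  H <- ncol(cts)
  if (H < 7 * 24) stop("at least 7 days of hourly counts are required")
  if (is.null(fitHours)) fitHours <- rep(TRUE, H)
  hod <- hour_of_day(series)
  fitted <- t(vapply(seq_len(nrow(cts)), function(d)
    fit_hod_poly(cts[d, ], hod, degree, which(fitHours & !is.na(cts[d, ]))),
    numeric(H)))
  dimnames(fitted) <- dimnames(cts)
  new_detrended(series, fitted, cts - fitted, "polynomial",
                list(degree = degree))
}

#' Select the hour-of-day polynomial degree by a temporal 80/20 split
#'
#' Fits the hour-of-day polynomial on the first 80\% of hours for every
#' candidate degree and returns the degree with the lowest squared error
#' on the remaining 20\% (summed over channels). Deterministic: the split
#' is temporal, not random.
#'
#' @inheritParams polynomialDetrend
#' @param degrees candidate degrees (default 2:10).
#' @param trainFrac fraction of hours in the fitting split.
#' @return the selected degree (integer).
#' @export
selectPolynomialDegree <- function(series, degrees = 2:10, trainFrac = 0.8) {
  cts <- detectorCounts(series)
  H <- ncol(cts)
  if (H < 7 * 24) stop("at least 7 days of hourly counts are required")
  hod <- hour_of_day(series)
  nTrain <- floor(H * trainFrac)
  trainIdx <- seq_len(H) <= nTrain
  err <- vapply(degrees, function(deg) {
    sum(vapply(seq_len(nrow(cts)), function(d) {
      ok <- !is.na(cts[d, ])
      f <- fit_hod_poly(cts[d, ], hod, deg, which(trainIdx & ok))
      sum((cts[d, !trainIdx & ok] - f[!trainIdx & ok])^2)
    }, 0))
  }, 0)
  # ties (e.g. an exactly polynomial profile) resolve to the lowest degree
  as.integer(min(degrees[err <= min(err) * (1 + 1e-8) + 1e-12]))
}

# Accumulate the band-pass wavelet reconstruction of x (demeaned) over the
# given periods; returns the raw (unnormalised) sum of Re(W)/sqrt(s).
recon_sum <- function(Xhat, periods, N) {
  r <- numeric(N)
  for (p in periods) {
    s <- period_to_scale(p)
    r <- r + Re(cwt_one_scale(Xhat, s, N)[, 1]) / sqrt(s)
  }
  r
}

#' Remove the 24-h components by wavelet decomposition
#'
#' Decomposes each channel with the Morlet continuous wavelet transform
#' (log-spaced scales, 24 voices per octave, periods from 2 h to half the
#' span) and recomposes it with the scales around 24 h zeroed. The
#' estimated diurnal component is the band-limited reconstruction over
#' periods \code{24 * [1/(1+band), 1+band]} hours; the overall
#' reconstruction factor is calibrated per channel by least squares
#' against the full-set recomposition, absorbing the discretisation of
#' the scale grid. Because only signal features captured by the wavelet
#' family contribute, reconstruction is not exact; unlike the polynomial
#' method, compound near-24-h components (e.g. 23.8 h) are removed too.
#'
#' The default band (\code{band = 0.75}, i.e. 13.7-42 h) covers the
#' spectral bandwidth of the Morlet-6 wavelet around 24 h: a narrower
#' band (such as +/-10\%) carries less than half of a pure 24-h
#' component's wavelet amplitude and cannot remove it.
#'
#' @param series a [DetectorSeries-class] with >= 7 days of data.
#' @param band fractional half-width of the removed period band.
#' @return a [DetrendedSeries-class] with \code{fitted} (the removed
#'   diurnal component) and \code{residual = counts - fitted}.
#' @export
waveletDetrend <- function(series, band = 0.75) {
  cts <- detectorCounts(series)
  H <- ncol(cts)
  if (H < 7 * 24) stop("at least 7 days of hourly counts are required")
  periods <- default_periods(H)
  inBand <- periods >= 24 / (1 + band) & periods <= 24 * (1 + band)
  if (!any(inBand)) stop("no wavelet scale falls in the removal band")
  npad <- next_pow2(H)
  fitted <- matrix(0, nrow(cts), H, dimnames = dimnames(cts))
  for (d in seq_len(nrow(cts))) {
    x <- cts[d, ]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    mu <- mean(x)
    xd <- x - mu
    Xhat <- stats::mvfft(matrix(c(xd, numeric(npad - H)), ncol = 1))
    rAll <- recon_sum(Xhat, periods, H)
    rBand <- recon_sum(Xhat, periods[inBand], H)
    denom <- sum(rAll^2)
    cc <- if (denom > 0) sum(rAll * xd) / denom else 0
    fitted[d, ] <- cc * rBand
  }
  new_detrended(series, fitted, cts - fitted, "wavelet", list(band = band))
}
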