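#' Pearson correlation with the t-test the model evaluation uses
#'
#' Sample Pearson R between prediction and observation with a two-tailed
#' t-test of the null R = 0: \eqn{t = R\sqrt{n-2}/\sqrt{1-R^2}} on
#' \eqn{n-2} degrees of freedom. Pairs with missing values are dropped
#' first.
#'
#' @param pred,obs paired numeric vectors (n >= 3 after NA removal).
#' @return list with \code{R}, \code{t}, \code{dof} (= n - 2), \code{p},
#'   \code{n}. A zero-variance input yields \code{R = NA} with
#'   \code{degenerate = TRUE}.
#' @export
pearsonRTest <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  x <- pred[ok]; y <- obs[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(R = NA_real_, t = NA_real_, dof = n - 2L, p = NA_real_,
                n = n, degenerate = TRUE))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(R = r, t = tt, dof = n - 2L, p = p, n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up procedure for independent or positively correlated tests:
#' rejects the hypotheses with the \code{k} smallest p-values where
#' \code{k} is the largest \code{i} with \code{p_(i) <= alpha * i / m}.
#' Adjusted p-values come from \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param alpha FDR threshold (default 0.05).
#' @return list with logical \code{rejected} and numeric \code{adjusted},
#'   both in input order.
#' @export
bhFDR <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  ps <- pvals[ord]
  below <- which(ps <= alpha * seq_len(m) / m)
  rejected <- rep(FALSE, m)
  if (length(below)) rejected[ord[seq_len(max(below))]] <- TRUE
  list(rejected = rejected, adjusted = stats::p.adjust(pvals, "BH"))
}

#' Daily-binned correlation (the diurnal-rhythm-free check)
#'
#' Sums prediction and observation within calendar days and correlates
#' the daily totals, removing any contribution of a shared 24-h cycle to
#' the hourly correlation. Days with any masked or missing hour are
#' dropped entirely to avoid biased sums.
#'
#' @param pred,obs paired hourly vectors.
#' @param hourIndex epoch hour of each entry (day = \code{hourIndex \%/\%
#'   24}).
#' @param mask logical: hours to include (e.g. behavioral-data presence);
#'   default all.
#' @return list as [pearsonRTest()] plus \code{nDays}.
#' @export
dailyBinnedCorrelation <- function(pred, obs, hourIndex,
                                   mask = rep(TRUE, length(pred))) {
  ok <- mask & is.finite(pred) & is.finite(obs)
  day <- hourIndex %/% 24L
  full <- tapply(ok, day, sum) == 24L
  days <- as.integer(names(full))[full]
  if (length(days) < 5L)
    stop("need at least 5 complete days for daily binning")
  keep <- day %in% days
  ps <- tapply(pred[keep], day[keep], sum)
  os <- tapply(obs[keep], day[keep], sum)
  r <- pearsonRTest(as.numeric(ps), as.numeric(os))
  r$nDays <- length(days)
  r
}

#' Detector sparsity
#'
#' The fraction of recorded hours with zero detections, per
#' detector-channel pair: 1 means the detector was never active, 0 means
#' at least one event every hour. Device-gap hours (NA) are excluded from
#' the denominator.
#'
#' @param series a [DetectorSeries-class].
#' @return named numeric vector in [0, 1].
#' @export
detectorSparsity <- function(series) {
  cts <- detectorCounts(series)
  apply(cts, 1, function(x) mean(x == 0, na.rm = TRUE))
}

#' Evaluate a trained model on its held-out windows
#'
#' Computes, per output channel, the Pearson R (with t-test), RMSE and
#' daily-binned correlation between the model's maximum-likelihood point
#' estimates and the observed targets on the test split, restricted to
#' windows with behavioral data in at least one of the 9 context bins.
#' BH-FDR decisions at \code{alpha} are made across the channels of this
#' report (the correction family can be widened by pooling reports and
#' calling [bhFDR()] directly).
#'
#' @param model a trained [JidModel-class].
#' @param windows the [ContextWindowSet-class] the model was trained on.
#' @param alpha FDR threshold.
#' @return a data.frame with one row per channel: \code{label},
#'   \code{detector}, \code{type}, \code{R}, \code{t}, \code{dof},
#'   \code{p}, \code{fdrRejected}, \code{rmse}, \code{n}, \code{RDaily},
#'   \code{pDaily}.
#' @export
evaluateModel <- function(model, windows, alpha = 0.05) {
  if (!model@trained) stop("model is not trained")
  cfg <- model@config
  C <- cfg$nOutputChannels; K <- cfg$nMixture
  idx <- which(!windows@isTrain)
  if (!length(idx)) stop("no test windows")
  raw <- forward_windows(cfg, model@params, model@state, windows, idx)
  estZ <- point_estimates_raw(raw, C, K)
  info <- windows@targetInfo
  mask <- windows@anyPresent[idx]
  hours <- windows@targetHour[idx]
  out <- vector("list", C)
  for (cc in seq_len(C)) {
    pred <- estZ[, cc] * info$sd[cc] + info$mean[cc]
    obs <- windows@targets[idx, cc] * info$sd[cc] + info$mean[cc]
    r <- pearsonRTest(pred[mask], obs[mask])
    daily <- tryCatch(
      dailyBinnedCorrelation(pred, obs, hours, mask),
      error = function(e) list(R = NA_real_, p = NA_real_))
    out[[cc]] <- data.frame(
      label = info$label[cc], detector = info$detector[cc],
      type = info$type[cc], R = r$R, t = r$t, dof = r$dof, p = r$p,
      rmse = sqrt(mean((pred[mask] - obs[mask])^2)), n = r$n,
      RDaily = daily$R, pDaily = daily$p)
  }
  report <- do.call(rbind, out)
  fd <- rep(FALSE, C)
  okp <- is.finite(report$p)
  if (any(okp)) fd[okp] <- bhFDR(report$p[okp], alpha)$rejected
  report$fdrRejected <- fd
  report[, c("label", "detector", "type", "R", "t", "dof", "p",
             "fdrRejected", "rmse", "n", "RDaily", "pDaily")]
}

#' Relate model performance to detector activity and behavioral density
#'
#' Correlates per-detector model performance (R) against detector
#' sparsity and against mean JID entropy, each with the [pearsonRTest()]
#' t-test -- the diagnostic asking whether performance is limited by how
#' often the detector fires or by how rich the behavioral space is.
#'
#' @param performance data.frame with columns \code{R} (model performance
#'   per detector) and \code{sparsity}, and optionally \code{entropy}.
#' @return list of [pearsonRTest()] results (\code{sparsity}, and
#'   \code{entropy} when supplied); degenerate (constant) predictors are
#'   flagged in the result.
#' @export
performanceVsActivity <- function(performance) {
  if (nrow(performance) < 4L)
    stop("need at least 4 detector-level results")
  out <- list(sparsity = pearsonRTest(performance$R, performance$sparsity))
  if (!is.null(performance$entropy))
    out$entropy <- pearsonRTest(performance$R, performance$entropy)
  out
}
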