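#' The JID grid axis
#'
#' The joint interval distribution discretises consecutive log10
#' inter-touch-interval pairs onto a 50x50 grid spanning log10-ITI 1.5 to 5
#' (30 ms to 100 s). Bin centers sit at the midpoints of 50 equal bins, so
#' the first center is 1.535 and the spacing is 0.07.
#'
#' @return numeric vector of the 50 bin centers (log10 ms).
#' @export
jidAxis <- function() {
  width <- (5 - 1.5) / 50
  seq(1.5 + width / 2, by = width, length.out = 50)
}

JID_CELL_AREA <- ((5 - 1.5) / 50)^2

#' JIDGrid: one discretised joint interval distribution
#'
#' @slot values 50x50 nonnegative matrix summing to 1 (rows index the
#'   earlier interval \code{x_k}, columns the subsequent \code{x_{k+1}}).
#' @slot nPairs number of consecutive-ITI pairs behind the estimate.
#' @exportClass JIDGrid
setClass("JIDGrid", representation(values = "matrix", nPairs = "integer"))

setValidity("JIDGrid", function(object) {
  v <- object@values
  if (!all(dim(v) == c(50L, 50L))) return("values must be 50x50")
  if (any(v < 0)) return("values must be nonnegative")
  if (object@nPairs >= 1L && abs(sum(v) - 1) > 1e-9)
    return("values must sum to 1")
  TRUE
})

setMethod("show", "JIDGrid", function(object) {
  i <- arrayInd(which.max(object@values), c(50L, 50L))
  ax <- jidAxis()
  cat(sprintf("JIDGrid from %d ITI pairs; mode near (%.3f, %.3f) log10 ms\n",
              object@nPairs, ax[i[1]], ax[i[2]]))
})

#' @rdname JIDGrid-class
#' @param x a JIDGrid
#' @export
jidValues <- function(x) x@values

#' Split a touch log into usage sessions
#'
#' A usage session is the period between a screen-on and the next
#' screen-off event; only touches inside a session contribute inter-touch
#' intervals. Touches outside any session (including before the first
#' screen-on) are discarded. A screen-on that is never matched by a
#' screen-off is closed at the last event of the log. Repeated screen-on
#' events inside an open session are ignored, as are stray screen-off
#' events.
#'
#' Each session's category is the majority category (via the log's
#' category map) among its touches, with ties and unmapped apps counting
#' as NonSocial.
#'
#' @param log a [TouchLog-class]
#' @return a data.frame with one row per session: \code{start}, \code{end}
#'   (ms), \code{nTouches}, \code{category}, and a list-column
#'   \code{touches} of touch timestamp vectors.
#' @export
sessionize <- function(log) {
  ev <- touchEvents(log)
  cm <- categoryMap(log)
  empty <- data.frame(start = numeric(), end = numeric(),
                      nTouches = integer(), category = character())
  empty$touches <- list()
  if (!nrow(ev)) return(empty)
  kind <- ev$kind; ts <- ev$timestamp_ms
  scr <- which(kind != "touch")
  starts <- numeric(length(scr)); ends <- numeric(length(scr))
  nS <- 0L; open <- FALSE; s0 <- NA_real_
  for (i in scr) {
    if (kind[i] == "screen_on") {
      if (!open) { open <- TRUE; s0 <- ts[i] }
    } else if (open) {
      nS <- nS + 1L; starts[nS] <- s0; ends[nS] <- ts[i]; open <- FALSE
    }
  }
  if (open) {  # unmatched screen_on closes at the last event
    nS <- nS + 1L; starts[nS] <- s0; ends[nS] <- ts[length(ts)]
  }
  if (!nS) return(empty)
  starts <- starts[seq_len(nS)]; ends <- ends[seq_len(nS)]
  touchIdx <- which(kind == "touch")
  tts <- ts[touchIdx]
  fi <- findInterval(tts, starts)
  ok <- fi >= 1L
  ok[ok] <- tts[ok] <= ends[fi[ok]]
  sid <- fi[ok]
  apps <- ev$app_id[touchIdx][ok]
  isSoc <- !is.na(cm[apps]) & cm[apps] == "Social"
  cats <- rep("NonSocial", nS)
  if (length(sid)) {
    agg <- rowsum(cbind(as.numeric(isSoc), 1), sid)
    idv <- as.integer(rownames(agg))
    cats[idv[agg[, 1] > agg[, 2] / 2]] <- "Social"
  }
  touches <- rep(list(numeric(0)), nS)
  spl <- split(tts[ok], sid)
  touches[as.integer(names(spl))] <- spl
  out <- data.frame(start = starts, end = ends,
                    nTouches = lengths(touches), category = cats)
  out$touches <- touches
  out
}

#' Consecutive ITI pairs from sessionized touches
#'
#' Within each session with n touches there are n-1 inter-touch intervals
#' and n-2 consecutive pairs (x_k, x_{k+1}). Each pair is assigned to the
#' clock hour containing the touch that terminates interval k (the middle
#' touch of the triplet). Intervals never span a screen-off/screen-on gap.
#'
#' Degenerate zero-length intervals (coincident timestamps) cannot be
#' log-transformed and are dropped with their pairs.
#'
#' @param sessions output of [sessionize()]
#' @return data.frame: \code{iti1}, \code{iti2} (ms), \code{hourIndex}
#'   (epoch hour), \code{category}.
#' @export
itiPairs <- function(sessions) {
  empty <- data.frame(iti1 = numeric(), iti2 = numeric(),
                      hourIndex = integer(), category = character())
  if (!nrow(sessions)) return(empty)
  tt <- unlist(sessions$touches, use.names = FALSE)
  sid <- rep(seq_len(nrow(sessions)), lengths(sessions$touches))
  n <- length(tt)
  if (n < 3L) return(empty)
  k <- seq_len(n - 2L)
  same <- sid[k] == sid[k + 2L]  # all three touches in one session
  k <- k[same]
  iti1 <- tt[k + 1L] - tt[k]
  iti2 <- tt[k + 2L] - tt[k + 1L]
  pos <- iti1 > 0 & iti2 > 0
  data.frame(iti1 = iti1[pos], iti2 = iti2[pos],
             hourIndex = as.integer(floor(tt[k + 1L][pos] / MS_PER_HOUR)),
             category = sessions$category[sid[k][pos]])
}

jid_matrix <- function(iti1, iti2, bandwidth = 0.1) {
  ax <- jidAxis()
  a <- log10(iti1); b <- log10(iti2)
  A <- stats::dnorm(outer(ax, a, "-") / bandwidth)   # 50 x n
  B <- stats::dnorm(outer(ax, b, "-") / bandwidth)
  g <- A %*% t(B)                                    # rows: x_k, cols: x_{k+1}
  s <- sum(g)
  if (s <= 0) matrix(0, 50, 50) else g / s
}

#' Estimate a joint interval distribution by 2D Gaussian KDE
#'
#' The density of consecutive log10-ITI pairs is estimated with a Gaussian
#' product kernel (bandwidth 0.1 in log10 units on each axis), evaluated at
#' the 50x50 grid centers of [jidAxis()], and renormalised to sum to 1.
#' Kernel mass falling outside the [1.5, 5] support is thereby lost and the
#' grid renormalised; pairs themselves are never excluded.
#'
#' @param pairs two-column matrix or data.frame of consecutive ITIs in ms
#'   (columns: x_k, x_{k+1}); all values must be positive.
#' @param bandwidth Gaussian kernel standard deviation in log10 units.
#' @return a [JIDGrid-class].
#' @examples
#' g <- estimateJID(cbind(rep(1000, 100), rep(1000, 100)))
#' which(jidValues(g) == max(jidValues(g)), arr.ind = TRUE)  # near (3, 3)
#' @export
estimateJID <- function(pairs, bandwidth = 0.1) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) stop("no ITI pairs: nothing to estimate this hour")
  if (any(pairs <= 0)) stop("ITIs must be positive")
  new("JIDGrid", values = jid_matrix(pairs[, 1], pairs[, 2], bandwidth),
      nPairs = nrow(pairs))
}

#' Build the hourly behavioral feature series from a touch log
#'
#' For every clock hour between the first and last event of the log, the
#' consecutive within-session ITI pairs assigned to that hour (see
#' [itiPairs()]) feed a JID estimate; a parallel Social-space grid uses
#' only pairs from Social-category sessions. Hours with no pairs get an
#' all-zero grid and \code{present = FALSE}.
#'
#' @param log a [TouchLog-class]
#' @param bandwidth KDE bandwidth (log10 units), default 0.1.
#' @param hourRange optional integer length-2 vector of epoch hours to
#'   cover (first, last); defaults to the span of the log.
#' @return an [HourlyFeatures-class] object.
#' @export
buildHourlyFeatures <- function(log, bandwidth = 0.1, hourRange = NULL) {
  ev <- touchEvents(log)
  if (!nrow(ev) && is.null(hourRange))
    stop("empty log and no hourRange given")
  if (is.null(hourRange))
    hourRange <- as.integer(floor(range(ev$timestamp_ms) / MS_PER_HOUR))
  hours <- seq.int(hourRange[1], hourRange[2])
  H <- length(hours)
  pr <- itiPairs(sessionize(log))
  jall <- matrix(0, 2500L, H)
  jsoc <- matrix(0, 2500L, H)
  nAll <- integer(H); nSoc <- integer(H)
  if (nrow(pr)) {
    pr <- pr[pr$hourIndex >= hourRange[1] & pr$hourIndex <= hourRange[2], ]
    idx <- split(seq_len(nrow(pr)), factor(pr$hourIndex, levels = hours))
    for (h in seq_len(H)) {
      ii <- idx[[h]]
      if (length(ii)) {
        jall[, h] <- as.vector(jid_matrix(pr$iti1[ii], pr$iti2[ii], bandwidth))
        nAll[h] <- length(ii)
        ss <- ii[pr$category[ii] == "Social"]
        if (length(ss)) {
          jsoc[, h] <- as.vector(jid_matrix(pr$iti1[ss], pr$iti2[ss], bandwidth))
          nSoc[h] <- length(ss)
        }
      }
    }
  }
  se <- SummarizedExperiment(
    assays = list(jidAll = jall, jidSocial = jsoc),
    colData = DataFrame(hourIndex = hours,
                        presentAll = nAll > 0L, presentSocial = nSoc > 0L,
                        nPairsAll = nAll, nPairsSocial = nSoc))
  metadata(se)$axis <- jidAxis()
  metadata(se)$bandwidth <- bandwidth
  new("HourlyFeatures", se)
}

#' Differential entropy of a JID (bits)
#'
#' Approximates the differential entropy
#' \eqn{-\int\int P \log_2 P \, dx_k dx_{k+1}} of the density underlying a
#' discretised grid: \eqn{-\sum p \log_2(p / A)} over cells with
#' probability mass \eqn{p > 0}, where \eqn{A = (3.5/50)^2} is the cell
#' area in squared log10 units. A uniform density over the full support
#' gives \eqn{\log_2 12.25 \approx 3.615} bits.
#'
#' @param grid a [JIDGrid-class], or a 50x50 matrix of cell masses summing
#'   to 1.
#' @return entropy in bits; \code{NA} for an all-zero (absent-hour) grid.
#' @export
jidEntropy <- function(grid) {
  v <- if (is(grid, "JIDGrid")) grid@values else as.matrix(grid)
  s <- sum(v)
  if (s <= 0) return(NA_real_)
  p <- v[v > 0]
  -sum(p * log2(p / JID_CELL_AREA))
}

#' Subject-level mean JID entropy
#'
#' The behavioral-space density diagnostic: the mean of [jidEntropy()]
#' across present hours of an [HourlyFeatures-class] series.
#'
#' @param features an [HourlyFeatures-class]
#' @param space \code{"all"} or \code{"social"}
#' @return mean entropy in bits (NA if no hour is present).
#' @export
meanJidEntropy <- function(features, space = c("all", "social")) {
  space <- match.arg(space)
  m <- if (space == "all") jidAll(features) else jidSocial(features)
  pres <- presentHours(features, space)
  if (!any(pres)) return(NA_real_)
  mean(apply(m[, pres, drop = FALSE], 2, function(col) {
    p <- col[col > 0]
    -sum(p * log2(p / JID_CELL_AREA))
  }))
}
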