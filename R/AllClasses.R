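#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData assayNames
NULL

MS_PER_HOUR <- 3600e3

#' TouchLog: a raw smartphone touchscreen event log
#'
#' Ordered per-event records of screen-on/screen-off transitions and
#' touchscreen touches, each touch carrying the identifier of the app in
#' use, plus a map assigning each app to the \code{"Social"} or
#' \code{"NonSocial"} category.
#'
#' @slot events a \code{data.frame} with columns \code{timestamp_ms}
#'   (numeric, milliseconds since epoch, non-decreasing), \code{kind}
#'   (one of \code{"touch"}, \code{"screen_on"}, \code{"screen_off"}) and
#'   \code{app_id} (character; \code{NA} allowed for screen events).
#' @slot categoryMap named character vector mapping \code{app_id} to
#'   \code{"Social"} or \code{"NonSocial"}; unmapped apps are treated as
#'   NonSocial.
#'
#' @seealso [TouchLog()], [sessionize()], [buildHourlyFeatures()]
#' @exportClass TouchLog
setClass("TouchLog",
  representation(events = "data.frame", categoryMap = "character"))

setValidity("TouchLog", function(object) {
  ev <- object@events
  msgs <- character()
  need <- c("timestamp_ms", "kind", "app_id")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (!is.numeric(ev$timestamp_ms) || anyNA(ev$timestamp_ms))
      msgs <- c(msgs, "timestamp_ms must be numeric and non-missing")
    else if (is.unsorted(ev$timestamp_ms))
      msgs <- c(msgs, "timestamps must be non-decreasing")
    bad <- setdiff(unique(as.character(ev$kind)),
                   c("touch", "screen_on", "screen_off"))
    if (length(bad))
      msgs <- c(msgs, paste("unknown event kind:", paste(bad, collapse = ", ")))
  }
  cm <- object@categoryMap
  if (length(cm)) {
    if (is.null(names(cm)) || any(names(cm) == ""))
      msgs <- c(msgs, "categoryMap must be a named vector")
    badc <- setdiff(unique(cm), c("Social", "NonSocial"))
    if (length(badc))
      msgs <- c(msgs, "categoryMap values must be Social or NonSocial")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TouchLog
#'
#' @param events data.frame with columns \code{timestamp_ms}, \code{kind},
#'   \code{app_id}. Rows are sorted by timestamp if needed (with a warning,
#'   since out-of-order logs usually indicate an upstream problem).
#' @param categoryMap named character vector (\code{app_id ->}
#'   \code{"Social"}/\code{"NonSocial"}); may be empty.
#' @return a [TouchLog-class] object.
#' @examples
#' ev <- data.frame(
#'   timestamp_ms = c(0, 100, 400, 900, 2000),
#'   kind = c("screen_on", "touch", "touch", "touch", "screen_off"),
#'   app_id = c(NA, "app.a", "app.a", "app.a", NA))
#' TouchLog(ev, c(app.a = "Social"))
#' @export
TouchLog <- function(events, categoryMap = character()) {
  events$kind <- as.character(events$kind)
  events$app_id <- as.character(events$app_id)
  if (nrow(events) && is.unsorted(events$timestamp_ms)) {
    warning("touch log events were not sorted by timestamp; reordering")
    events <- events[order(events$timestamp_ms), , drop = FALSE]
  }
  rownames(events) <- NULL
  new("TouchLog", events = events, categoryMap = categoryMap)
}

setMethod("show", "TouchLog", function(object) {
  ev <- object@events
  cat("TouchLog with", nrow(ev), "events\n")
  if (nrow(ev)) {
    cat(sprintf("  span: %.1f h; touches: %d; sessions (screen_on): %d\n",
                (max(ev$timestamp_ms) - min(ev$timestamp_ms)) / MS_PER_HOUR,
                sum(ev$kind == "touch"), sum(ev$kind == "screen_on")))
    cat("  apps:", length(unique(ev$app_id[ev$kind == "touch"])),
        "| category map entries:", length(object@categoryMap), "\n")
  }
})

#' HourlyFeatures: per-hour joint interval distributions
#'
#' A \linkS4class{SummarizedExperiment} whose columns are consecutive clock
#' hours and whose rows are the 2500 pixels of the 50x50 JID grid.
#' Assays \code{jidAll} and \code{jidSocial} hold the vectorised grids
#' (column-major over the grid; each present column sums to 1, absent hours
#' are all-zero). Column data carry \code{hourIndex} (epoch hour),
#' \code{presentAll}/\code{presentSocial} and pair counts. Metadata stores
#' the shared log10-ITI axis and the KDE bandwidth.
#'
#' @exportClass HourlyFeatures
setClass("HourlyFeatures", contains = "SummarizedExperiment")

setValidity("HourlyFeatures", function(object) {
  if (!all(c("jidAll", "jidSocial") %in% assayNames(object)))
    return("assays jidAll and jidSocial are required")
  if (nrow(object) != 2500L)
    return("HourlyFeatures must have 2500 rows (50x50 JID pixels)")
  cd <- colData(object)
  need <- c("hourIndex", "presentAll", "presentSocial", "nPairsAll", "nPairsSocial")
  if (!all(need %in% names(cd)))
    return(paste("colData must have", paste(need, collapse = ", ")))
  if (ncol(object) > 1 && any(diff(cd$hourIndex) != 1L))
    return("hourIndex must be consecutive")
  TRUE
})

#' DetectorSeries: hourly epileptiform detection counts
#'
#' A \linkS4class{SummarizedExperiment} with one row per detector-channel
#' pair (at most 4, matching the implanted device's two pattern detectors
#' on two bipolar channels) and one column per clock hour. Assay
#' \code{counts} holds nonnegative integer hourly detection counts; after
#' detrending, assays \code{fitted} (estimated 24-h component) and
#' \code{residual} are added (see [polynomialDetrend()] and
#' [waveletDetrend()]).
#'
#' @exportClass DetectorSeries
setClass("DetectorSeries", contains = "SummarizedExperiment")

setValidity("DetectorSeries", function(object) {
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  if (nrow(object) < 1L || nrow(object) > 4L)
    return("between 1 and 4 detector-channel pairs are supported")
  cts <- assay(object, "counts")
  fin <- cts[is.finite(cts)]
  if (any(fin < 0) || any(fin != round(fin)))
    return("counts must be nonnegative integers (NA = device gap)")
  if (!"hourIndex" %in% names(colData(object)))
    return("colData must have hourIndex")
  if (ncol(object) > 1 && any(diff(colData(object)$hourIndex) != 1L))
    return("hourIndex must be consecutive")
  TRUE
})

#' DetrendedSeries: detector counts with a 24-h component removed
#'
#' A [DetectorSeries-class] carrying, in addition to \code{counts}, the
#' assays \code{fitted} (the estimated diurnal component) and
#' \code{residual}, plus the detrending method in \code{metadata()$method}.
#' For the polynomial method \code{counts == fitted + residual} exactly.
#'
#' @exportClass DetrendedSeries
setClass("DetrendedSeries", contains = "DetectorSeries")

setValidity("DetrendedSeries", function(object) {
  if (!all(c("fitted", "residual") %in% assayNames(object)))
    return("assays 'fitted' and 'residual' are required")
  if (!metadata(object)$method %in% c("polynomial", "wavelet"))
    return("method must be 'polynomial' or 'wavelet'")
  TRUE
})

#' Periodogram: wavelet power spectrum of an hourly series
#'
#' Power is the square root of the time-average of the wavelet transform
#' modulus at each scale (cone of influence excluded). When a shuffle
#' bootstrap has been attached, \code{ciUpper} holds the per-period upper
#' quantile under random permutation of the series and \code{significant}
#' flags \code{power > ciUpper}.
#'
#' @slot periods numeric, strictly increasing periods in hours.
#' @slot power nonnegative numeric, one value per period.
#' @slot ciUpper numeric or NA, bootstrap threshold per period.
#' @slot significant logical per period.
#' @slot level confidence level in percent (e.g. 95 or 99.9), NA if no
#'   bootstrap was run.
#' @slot nShuffles number of permutations used (0 if none).
#' @exportClass Periodogram
setClass("Periodogram",
  representation(periods = "numeric", power = "numeric", ciUpper = "numeric",
                 significant = "logical", level = "numeric",
                 nShuffles = "integer"))

setValidity("Periodogram", function(object) {
  if (length(object@power) != length(object@periods))
    return("power and periods lengths differ")
  if (any(diff(object@periods) <= 0))
    return("periods must be strictly increasing")
  if (any(object@power < 0, na.rm = TRUE))
    return("power must be nonnegative")
  TRUE
})

setMethod("show", "Periodogram", function(object) {
  cat(sprintf("Periodogram: %d periods, %.2f-%.1f h\n",
              length(object@periods), min(object@periods), max(object@periods)))
  pk <- object@periods[which.max(object@power)]
  cat(sprintf("  peak power %.4g at %.1f h\n", max(object@power), pk))
  if (object@nShuffles > 0L)
    cat(sprintf("  bootstrap: %d shuffles, %.1f%% level, %d significant periods\n",
                object@nShuffles, object@level, sum(object@significant)))
})

#' CyclePowerMap: per-pixel cycle power over the JID grid
#'
#' Wavelet power at a single period (typically 24 h) for each of the 2500
#' JID pixel time series, with a per-pixel shuffle-bootstrap significance
#' test and cluster-level masking: 4-connected significant regions that do
#' not contain a fully significant 2x2 square are masked out.
#'
#' @slot period the analysed period, hours.
#' @slot power 50x50 nonnegative matrix.
#' @slot significant 50x50 logical, raw per-pixel test.
#' @slot mask 50x50 logical; TRUE = shown (significant and in a surviving
#'   cluster).
#' @slot level confidence level in percent.
#' @slot nShuffles shuffles per pixel.
#' @exportClass CyclePowerMap
setClass("CyclePowerMap",
  representation(period = "numeric", power = "matrix", significant = "matrix",
                 mask = "matrix", level = "numeric", nShuffles = "integer"))

setMethod("show", "CyclePowerMap", function(object) {
  cat(sprintf("CyclePowerMap at %.1f h: %d/%d pixels significant, %d shown after 2x2 cluster mask\n",
              object@period, sum(object@significant), length(object@significant),
              sum(object@mask)))
})

#' ContextWindowSet: model-ready 9-hour behavioral windows with targets
#'
#' Pairs each target hour with its 9-frame behavioral context (hourly
#' 50x50x2 JID tensors: all-ITI and Social channels), the per-channel
#' regression targets (z-scored raw counts and their 24-h-detrended
#' counterparts), the temporal train/test split and the scaling constants
#' needed to map predictions back to counts.
#'
#' @slot features numeric matrix, 5000 x H: column h is the vectorised
#'   50x50x2 input tensor for hour h (all-ITI grid then Social grid).
#' @slot presence logical H x 2 matrix (all, social).
#' @slot hourIndex integer epoch hour per feature column.
#' @slot targetHour integer vector, epoch hour of each window's target.
#' @slot frameHours integer n x 9 matrix of feature-column indices per window.
#' @slot targets numeric n x C matrix of z-scored targets.
#' @slot targetInfo data.frame: per output channel, detector label, type
#'   (\code{raw}/\code{detrended}), z-scoring mean and sd (train split).
#' @slot alignment \code{"centered"} (t-4..t+4) or \code{"preceding"}
#'   (t-9..t-1).
#' @slot isTrain logical per window; test windows are strictly later.
#' @slot anyPresent logical per window: at least one of the 9 context bins
#'   has behavioral data (evaluation is restricted to these windows).
#' @exportClass ContextWindowSet
setClass("ContextWindowSet",
  representation(features = "matrix", presence = "matrix",
                 hourIndex = "integer", targetHour = "integer",
                 frameHours = "matrix", targets = "matrix",
                 targetInfo = "data.frame", alignment = "character",
                 isTrain = "logical", anyPresent = "logical"))

setValidity("ContextWindowSet", function(object) {
  if (nrow(object@features) != 5000L)
    return("features must have 5000 rows (50x50x2)")
  if (!object@alignment %in% c("centered", "preceding"))
    return("alignment must be 'centered' or 'preceding'")
  if (ncol(object@frameHours) != 9L)
    return("frameHours must have 9 columns")
  n <- length(object@targetHour)
  if (nrow(object@frameHours) != n || nrow(object@targets) != n ||
      length(object@isTrain) != n || length(object@anyPresent) != n)
    return("window-level slots disagree in length")
  if (n && any(object@isTrain) && any(!object@isTrain) &&
      max(object@targetHour[object@isTrain]) >=
      min(object@targetHour[!object@isTrain]))
    return("test windows must be strictly later than training windows")
  TRUE
})

setMethod("show", "ContextWindowSet", function(object) {
  cat(sprintf("ContextWindowSet: %d windows (%s alignment), %d train / %d test\n",
              length(object@targetHour), object@alignment,
              sum(object@isTrain), sum(!object@isTrain)))
  cat(sprintf("  %d output channels; %d windows with any behavioral data\n",
              ncol(object@targets), sum(object@anyPresent)))
})

#' JidModel: the convolutional-recurrent mixture-density network
#'
#' A per-subject model mapping a 9-frame sequence of 50x50x2 hourly JID
#' tensors to a 3-component Gaussian mixture per output channel per hour.
#' A shared convolutional extractor (a compact 4-block strided network or
#' a ResNet-50 adapted to 50x50x2 input) embeds each frame; a 3-layer
#' LSTM with 50 units integrates the 9 steps; per-channel linear heads emit
#' 9 mixture values (3 means, 3 standard deviations, 3 weights).
#'
#' @slot config model configuration list (see [buildModel()]).
#' @slot params list of numeric parameter arrays.
#' @slot state list of non-trained state (batch-norm running moments).
#' @slot trained logical.
#' @slot history data.frame of per-epoch train/validation loss.
#' @slot targetInfo data.frame copied from the training windows (channel
#'   labels and z-scoring constants); empty until trained.
#' @exportClass JidModel
setClass("JidModel",
  representation(config = "list", params = "list", state = "list",
                 trained = "logical", history = "data.frame",
                 targetInfo = "data.frame"))

setMethod("show", "JidModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("JidModel (%s extractor): %s parameters, %s\n",
              object@config$extractor, format(np, big.mark = ","),
              if (object@trained) sprintf("trained (%d epochs)", nrow(object@history))
              else "untrained"))
  if (object@trained && nrow(object@targetInfo))
    cat("  output channels:",
        paste(object@targetInfo$label, collapse = ", "), "\n")
})
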