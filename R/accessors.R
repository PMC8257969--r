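#' @rdname TouchLog-class
#' @param object,x a TouchLog / package object
#' @export
setGeneric("touchEvents", function(x) standardGeneric("touchEvents"))

#' @rdname TouchLog-class
#' @export
setMethod("touchEvents", "TouchLog", function(x) x@events)

#' @rdname TouchLog-class
#' @export
setGeneric("categoryMap", function(x) standardGeneric("categoryMap"))

#' @rdname TouchLog-class
#' @export
setMethod("categoryMap", "TouchLog", function(x) x@categoryMap)

#' Accessors for HourlyFeatures
#'
#' \code{jidAll}/\code{jidSocial} return the 2500 x H assay matrices;
#' \code{hourIndex} the epoch-hour of each column; \code{presentHours} the
#' logical presence mask for the requested feature space.
#'
#' @param x a [HourlyFeatures-class] object (or [DetectorSeries-class] for
#'   \code{hourIndex}).
#' @param space \code{"all"} or \code{"social"}.
#' @return matrices / vectors as described.
#' @name HourlyFeatures-accessors
NULL

#' @rdname HourlyFeatures-accessors
#' @export
jidAll <- function(x) assay(x, "jidAll")

#' @rdname HourlyFeatures-accessors
#' @export
jidSocial <- function(x) assay(x, "jidSocial")

#' @rdname HourlyFeatures-accessors
#' @export
setGeneric("hourIndex", function(x) standardGeneric("hourIndex"))

#' @rdname HourlyFeatures-accessors
#' @export
setMethod("hourIndex", "SummarizedExperiment",
          function(x) colData(x)$hourIndex)

#' @rdname HourlyFeatures-accessors
#' @export
presentHours <- function(x, space = c("all", "social")) {
  space <- match.arg(space)
  if (space == "all") colData(x)$presentAll else colData(x)$presentSocial
}

#' Detector count accessor
#' @param x a [DetectorSeries-class]
#' @return the detectors-by-hours integer count matrix
#' @export
detectorCounts <- function(x) assay(x, "counts")

#' Detrended residual / fitted diurnal accessors
#' @param x a [DetrendedSeries-class]
#' @return the detectors-by-hours residual (or fitted) matrix
#' @export
detrendResidual <- function(x) assay(x, "residual")

#' @rdname detrendResidual
#' @export
fittedDiurnal <- function(x) assay(x, "fitted")

#' Periodogram accessors
#' @param x a [Periodogram-class]
#' @return \code{periodogramTable}: data.frame with period, power, ciUpper,
#'   significant; \code{peakPeriod}: the period (hours) of maximum power.
#' @export
periodogramTable <- function(x) {
  data.frame(period = x@periods, power = x@power, ciUpper = x@ciUpper,
             significant = x@significant)
}

#' @rdname periodogramTable
#' @export
peakPeriod <- function(x) x@periods[which.max(x@power)]
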