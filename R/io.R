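# Plain-CSV interchange formats: touch logs (timestamp_ms, kind, app_id),
# app category maps (app_id, category) and hourly detector counts
# (hour_start_iso, detector_id, count). Hour bins are half-open [h, h+1)
# on the local clock.

#' Read / write a touch log CSV
#'
#' The dialect has header \code{timestamp_ms,kind,app_id} with kind one
#' of \code{touch}, \code{screen_on}, \code{screen_off}. Rows are sorted
#' on read (with a warning if reordering occurred); malformed rows raise
#' an error naming the line.
#'
#' @param path CSV file path.
#' @param categoryPath optional CSV with header \code{app_id,category}
#'   mapping apps to \code{Social}/\code{NonSocial}.
#' @return a [TouchLog-class].
#' @export
readTouchLog <- function(path, categoryPath = NULL) {
  ev <- utils::read.csv(path, colClasses = "character")
  need <- c("timestamp_ms", "kind", "app_id")
  if (!all(need %in% names(ev)))
    stop("touch log must have columns ", paste(need, collapse = ", "))
  ts <- suppressWarnings(as.numeric(ev$timestamp_ms))
  bad <- which(!is.finite(ts))
  if (length(bad))
    stop(sprintf("non-numeric timestamp at line %d of %s", bad[1] + 1L,
                 path))
  badk <- which(!ev$kind %in% c("touch", "screen_on", "screen_off"))
  if (length(badk))
    stop(sprintf("unknown event kind '%s' at line %d of %s",
                 ev$kind[badk[1]], badk[1] + 1L, path))
  cm <- character()
  if (!is.null(categoryPath)) {
    cmdf <- utils::read.csv(categoryPath, colClasses = "character")
    if (!all(c("app_id", "category") %in% names(cmdf)))
      stop("category map must have columns app_id, category")
    cm <- stats::setNames(cmdf$category, cmdf$app_id)
  }
  ev$app_id[ev$app_id == ""] <- NA_character_
  TouchLog(data.frame(timestamp_ms = ts, kind = ev$kind,
                      app_id = ev$app_id), cm)
}

#' @rdname readTouchLog
#' @param log a [TouchLog-class].
#' @export
writeTouchLog <- function(log, path, categoryPath = NULL) {
  ev <- touchEvents(log)
  ev$timestamp_ms <- format(ev$timestamp_ms, scientific = FALSE,
                            trim = TRUE)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(categoryPath)) {
    cm <- categoryMap(log)
    utils::write.csv(data.frame(app_id = names(cm), category = unname(cm)),
                     categoryPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

hour_to_iso <- function(hourIndex)
  format(as.POSIXct(hourIndex * 3600, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:00:00")

iso_to_hour <- function(iso) {
  t <- as.POSIXct(iso, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(t)) stop("unparseable hour_start_iso value")
  as.integer(as.numeric(t) %/% 3600)
}

#' Read / write hourly detector counts
#'
#' Long CSV with header \code{hour_start_iso,detector_id,count}; hours on
#' local-clock boundaries. On read a dense hourly grid is constructed
#' over the full span; hours absent from the file for a detector are
#' marked missing (NA, a device gap) -- distinct from an explicit zero
#' count. Duplicate (hour, detector) rows and negative counts are errors.
#'
#' @param path CSV file path.
#' @return a [DetectorSeries-class].
#' @export
readDetectorCounts <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "numeric"))
  need <- c("hour_start_iso", "detector_id", "count")
  if (!all(need %in% names(df)))
    stop("detector CSV must have columns ", paste(need, collapse = ", "))
  if (any(df$count < 0)) stop("negative detector count")
  if (any(df$count != round(df$count))) stop("non-integer detector count")
  h <- iso_to_hour(df$hour_start_iso)
  if (anyDuplicated(paste(h, df$detector_id)))
    stop("duplicate (hour, detector) rows")
  hours <- seq.int(min(h), max(h))
  dets <- sort(unique(df$detector_id))
  cts <- matrix(NA_real_, length(dets), length(hours),
                dimnames = list(dets, NULL))
  cts[cbind(match(df$detector_id, dets), h - hours[1] + 1L)] <- df$count
  se <- SummarizedExperiment(
    assays = list(counts = cts),
    rowData = DataFrame(detectorLabel = dets),
    colData = DataFrame(hourIndex = hours))
  new("DetectorSeries", se)
}

#' @rdname readDetectorCounts
#' @param series a [DetectorSeries-class].
#' @export
writeDetectorCounts <- function(series, path) {
  cts <- detectorCounts(series)
  hours <- hourIndex(series)
  labs <- rownames(cts)
  if (is.null(labs)) labs <- paste0("det", seq_len(nrow(cts)))
  df <- do.call(rbind, lapply(seq_len(nrow(cts)), function(d) {
    ok <- !is.na(cts[d, ])
    data.frame(hour_start_iso = hour_to_iso(hours[ok]),
               detector_id = labs[d], count = cts[d, ok])
  }))
  df <- df[order(df$hour_start_iso, df$detector_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
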