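# Shared fixture builders. Everything is generated in code; the heavier
# planted-coupling recovery experiment is memoised so several test files
# can share one training run.

# a touch log from explicit session specs: list(start_ms, itis_ms, app)
make_log <- function(sessions, categoryMap = c(social.app = "Social",
                                               other.app = "NonSocial")) {
  rows <- lapply(sessions, function(s) {
    tt <- s$start + cumsum(c(0, s$itis))
    data.frame(
      timestamp_ms = c(s$start - 100, tt, tt[length(tt)] + 100),
      kind = c("screen_on", rep("touch", length(tt)), "screen_off"),
      app_id = c(NA, rep(s$app, length(tt)), NA))
  })
  TouchLog(do.call(rbind, rows), categoryMap)
}

# a DetectorSeries from a counts matrix (detectors x hours)
make_detector_series <- function(counts, startHour = 0L) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  labs <- paste0("L1D", seq_len(nrow(counts)))
  rownames(counts) <- labs
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(detectorLabel = labs),
    colData = S4Vectors::DataFrame(
      hourIndex = seq.int(startHour, length.out = ncol(counts))))
  new("DetectorSeries", se)
}

# an HourlyFeatures object from explicit assay matrices (2500 x H)
make_features <- function(jall, jsoc = jall * 0, startHour = 0L) {
  H <- ncol(jall)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(jidAll = jall, jidSocial = jsoc),
    colData = S4Vectors::DataFrame(
      hourIndex = seq.int(startHour, length.out = H),
      presentAll = colSums(jall) > 0, presentSocial = colSums(jsoc) > 0,
      nPairsAll = as.integer(colSums(jall) > 0),
      nPairsSocial = as.integer(colSums(jsoc) > 0)))
  S4Vectors::metadata(se)$axis <- jidAxis()
  S4Vectors::metadata(se)$bandwidth <- 0.1
  new("HourlyFeatures", se)
}

# power at an exact Fourier frequency, the oracle used by detrending tests
fft_power_at <- function(x, period) {
  n <- length(x)
  k <- n / period  # integer when period divides the length
  Mod(stats::fft(x - mean(x))[k + 1])^2
}

# the planted-coupling recovery experiment shared by several tests:
# 180 simulated days, strong coupling of the fast-ITI JID mass to the
# detector rate, small extractor, centered alignment, 80/20 split
recovery_env <- new.env(parent = emptyenv())

get_recovery <- function() {
  if (!is.null(recovery_env$res)) return(recovery_env$res)
  cfg <- simulationConfig(durationDays = 180, couplingStrength = 0.8,
                          seed = 1L)
  ds <- makePairedDataset(cfg)
  w <- makeContextWindows(ds$features, ds$counts, "centered")
  m <- buildModel(2L, "small", seed = 1L)
  m <- trainModel(m, w, epochs = 10L, batchSize = 128L, seed = 1L)
  ev <- evaluateModel(m, w)
  recovery_env$res <- list(cfg = cfg, ds = ds, windows = w, model = m,
                           eval = ev)
  recovery_env$res
}
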