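# jidnet

Linking day-to-day smartphone touchscreen dynamics to hourly counts of
epileptiform discharges recorded by an implanted responsive
neurostimulator.

Implanted neurostimulators log, for each of up to four detector-channel
pairs, the hourly count of brief interictal epileptiform discharges —
continuously, for months to years of daily life. A smartphone running a
background logger captures a behavioral trace on the same clock: every
touchscreen touch timestamp, the screen-on/off events bounding each
usage session, and the app in use. `jidnet` implements the full analysis
connecting the two:

* **Behavioral features.** Consecutive inter-touch intervals (ITIs)
  within a session are summarised per clock hour as a *joint interval
  distribution* (JID): a 2-D Gaussian kernel density estimate
  (bandwidth 0.1) of P(log₁₀ x_{k+1}, log₁₀ x_k), discretised on a
  50×50 grid over log₁₀-ITI ∈ [1.5, 5] (30 ms–100 s), for all apps and
  for Social apps separately — a 50×50×2 tensor per hour.
* **Cyclicity.** Complex Morlet wavelet periodograms, power
  √(mean_t |W|), with shuffle-bootstrap significance thresholds — per
  detector series and per JID pixel (with 2×2-square cluster masking).
* **24-h detrending.** Hour-of-day polynomial fit (degree 5, selectable
  2–10) and wavelet-recomposition removal of the diurnal band.
* **Model.** A per-subject convolutional-recurrent mixture-density
  network: a shared extractor (ResNet-50 adapted to 50×50×2, or a
  compact 4-block network for desk-scale work) embeds each frame of a
  9-hour context (t−4…t+4, or t−9…t−1 for the time-causal variant), a
  3-layer LSTM(50) integrates the sequence, and per-channel heads emit a
  3-component Gaussian mixture per hour for each detector's raw and
  detrended counts. Trained by mixture negative log-likelihood with Adam
  on a temporal 80/20 split. The network (im2col convolution,
  batch-norm, BPTT, Adam) is implemented directly on R's BLAS — there is
  no deep-learning framework dependency — and all gradients are verified
  against finite differences in the test suite.
* **Attribution.** Gradient × input maps showing which regions of the
  behavioral space push a detector's predicted activity up or down.
* **Statistics.** Pearson R with t(n−2) tests, BH-FDR, RMSE,
  daily-binned correlation, detector sparsity, JID entropy.
* **Synthetic data.** A paired generator (sessions, ITI mixtures, 15 ms
  timestamp jitter, diurnal/multidien Poisson count cycles, behavioral
  gaps, and a configurable coupling from a JID sub-region to the count
  rate) with ground truth, so the whole pipeline validates end to end
  without access to patient data.

## Worked example

Simulate 60 days of paired data in which the fast-ITI mass of the
hourly JID drives the detector rate, then recover that coupling:

```r
library(jidnet)

cfg <- simulationConfig(durationDays = 60, couplingStrength = 0.8, seed = 42)
ds  <- makePairedDataset(cfg)     # log, features, counts, truth

detectorSparsity(ds$counts)
#>       L1D1
#> 0.01736111                      # detector silent in ~2% of hours
round(meanJidEntropy(ds$features), 2)
#> [1] 1.76                        # bits; uniform surface would be 3.61

pg <- bootstrapPeriodogram(detectorCounts(ds$counts)[1, ],
                           nShuffles = 200, level = 95, seed = 1)
pg
#> Periodogram: 204 periods, 2.00-703.5 h
#>   peak power 6.996 at 24.0 h
#>   bootstrap: 200 shuffles, 95.0% level, 19 significant periods

w <- makeContextWindows(ds$features, ds$counts, "centered")
w
#> ContextWindowSet: 1432 windows (centered alignment), 1145 train / 287 test
#>   2 output channels; 1431 windows with any behavioral data

m <- buildModel(2L, "small", seed = 42)
m <- trainModel(m, w, epochs = 10, batchSize = 128, seed = 42)
evaluateModel(m, w)[, c("label", "R", "t", "dof", "p", "rmse", "n")]
#>            label       R      t dof        p rmse   n
#> 1       L1D1.raw 0.30322 5.3719 285 1.62e-07 18.1 287
#> 2 L1D1.detrended 0.00532 0.0899 285 9.28e-01 17.4 287
```

The held-out hourly correlation for the raw channel (R = 0.30,
t(285) = 5.37, p = 1.6×10⁻⁷) shows the planted behavior–count coupling
is recovered from the touchscreen dynamics alone on even this short
simulation; the detrended channel is harder, as the planted coupling on
this fixture is largely diurnal. `gradientTimesInput(m, w, channel = 1)`
then localises the coupling to the fast-ITI corner of the JID, and
`predictSeries(m, ds$features)` reconstructs the full hourly trace.

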