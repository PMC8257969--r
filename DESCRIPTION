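Package: jidnet
Title: Linking Smartphone Touchscreen Dynamics to Hourly Epileptiform
    Discharge Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating day-to-day smartphone touchscreen behavior to
    hourly counts of epileptiform discharges logged by an implanted responsive
    neurostimulator. Touch logs are summarised per clock hour as joint interval
    distributions (JIDs): 50x50 kernel-density surfaces over consecutive
    log10 inter-touch-interval pairs, for all apps and for Social apps.
    Includes Morlet wavelet periodograms with shuffle-bootstrap significance
    for circadian and multidien cycles (per detector and per JID pixel),
    two 24-h detrending methods (hour-of-day polynomial and wavelet component
    removal), a convolutional-recurrent mixture-density network that
    reconstructs or forecasts hourly discharge counts from 9-h behavioral
    context windows, gradient-times-input attribution over the behavioral
    space, the associated evaluation statistics (Pearson R with t-tests,
    BH-FDR, RMSE, daily binning, sparsity, JID entropy), and a synthetic
    generator producing paired touch logs and detector series with planted
    cycles and behavior-count coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
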