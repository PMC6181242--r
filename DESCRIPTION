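Package: nirsreject
Title: Adaptive Acceptance-Rate-Controlled Epoch Rejection for Block-Design fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control for block-design functional near-infrared
    spectroscopy (fNIRS) hemoglobin time series. Implements three noise
    criteria (sudden amplitude change with recovery failure, excessive
    prestimulus baseline slope, and low inter-epoch correlation with an
    IQR-based outlier fence) combined into a sequential rejection engine
    whose rejections are bounded by an acceptance rate, i.e. a minimum
    number of surviving epochs, with noise-level ranking used for the
    final trim. Also provides a synthetic block-design signal generator
    (gamma hemodynamic response convolved with a boxcar, band-limited
    physiological noise, SNR-calibrated machine noise, recovery and
    non-recovery spikes, prestimulus baseline shifts), a statistical
    power simulation for epoch averaging under random rejection, and a
    grid-search harness for optimizing criterion thresholds against
    reproducibility targets and reference rejection labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
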