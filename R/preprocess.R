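#' Preprocessing configuration
#'
#' Linear detrending followed by a zero-phase Butterworth band-pass with
#' cut-off frequencies 0.01 and 0.8 Hz, removing slow baseline drift and
#' heartbeat pulsation respectively.
#'
#' @param band_low,band_high Band edges in Hz. Defaults 0.01 and 0.8.
#' @param filter_order Butterworth design order. Default 4.
#' @param zero_phase Forward-backward filtering (no epoch-relative latency
#'   shift). Default `TRUE`.
#' @param detrend_degree Polynomial degree of the detrend; only degree 1
#'   (a least-squares line) is supported.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 0.01, band_high = 0.8,
                              filter_order = 4L, zero_phase = TRUE,
                              detrend_degree = 1L) {
  if (detrend_degree != 1L) stop("only first-degree detrending is supported", call. = FALSE)
  if (!(band_low > 0 && band_low < band_high)) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase), detrend_degree = 1L),
            class = "preprocess_config")
}

# Subtract the least-squares line from a vector (closed form).
detrend_vector <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to detrend", call. = FALSE)
  t <- seq_len(n) - (n + 1) / 2          # centered time axis
  beta <- sum(t * x) / sum(t * t)
  x - mean(x) - beta * t
}

#' Remove linear drift from a recording
#'
#' Per channel, subtracts the least-squares first-degree polynomial fit over
#' the full record, so the output has zero mean and zero linear trend.
#'
#' @param rec An [continuous_recording()].
#' @return The detrended recording.
#' @export
detrend_linear <- function(rec) {
  stopifnot(inherits(rec, "fnirs_recording"))
  rec$values <- t(apply(rec$values, 1L, detrend_vector))
  rownames(rec$values) <- rec$channels
  rec
}

#' Band-pass filter a recording
#'
#' Applies the configured Butterworth band-pass (zero phase by default) to
#' every channel. See [bandpass_series()] for the filter realization.
#'
#' @param rec An [continuous_recording()].
#' @param config A [preprocess_config()].
#' @return The filtered recording.
#' @export
bandpass <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "fnirs_recording"), inherits(config, "preprocess_config"))
  nyq <- 1 / (2 * rec$grid$dt)
  if (config$band_high >= nyq) {
    stop("`band_high` must be below the Nyquist frequency", call. = FALSE)
  }
  rec$values <- t(apply(rec$values, 1L, bandpass_series, dt = rec$grid$dt,
                        low = config$band_low, high = config$band_high,
                        order = config$filter_order,
                        zero_phase = config$zero_phase))
  rownames(rec$values) <- rec$channels
  rec
}

#' Detrend and band-pass a recording
#'
#' The fixed preprocessing pipeline applied before epoching: first-degree
#' polynomial detrend, then band-pass.
#'
#' @param rec An [continuous_recording()].
#' @param config A [preprocess_config()].
#' @return The preprocessed recording.
#' @export
preprocess <- function(rec, config = preprocess_config()) {
  bandpass(detrend_linear(rec), config)
}

#' Normalize epoch baselines to zero
#'
#' Per epoch, subtracts the mean over the first `baseline_s` seconds of the
#' window (the 10-s baseline, not the full 13-s prestimulus), so the new
#' baseline mean is exactly zero. Idempotent.
#'
#' @param es An `epoch_set` from [extract_epochs()].
#' @return The epoch set with zeroed baselines.
#' @export
normalize_baseline <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  d <- es$design
  idx <- epoch_window_idx(es$times, -d$pre_s, -d$pre_s + d$baseline_s)
  base_means <- rowMeans(es$data[, idx, drop = FALSE])
  es$data <- es$data - base_means
  es
}

#' Signal-to-noise ratio of an epoch waveform
#'
#' `SNR = 20 log10(mu / sigma)` in dB, where `mu` is the mean over the
#' activation interval (4 s after stimulus onset to stimulus end) and
#' `sigma` the standard deviation over the baseline interval (10 s before
#' stimulus onset to onset). With non-positive `mu` the ratio has no real
#' logarithm and the SNR is reported as `NA` (undefined); a zero baseline
#' SD is a degenerate input and raises an error.
#'
#' @param x Numeric epoch waveform.
#' @param times Seconds relative to stimulus onset, one per sample.
#' @param stim_s Stimulus duration in seconds.
#' @return List with `snr_db`, `activation_mean`, `baseline_sd`.
#' @export
compute_snr <- function(x, times, stim_s) {
  act <- epoch_window_idx(times, 4, stim_s)
  base <- epoch_window_idx(times, -10, 0)
  if (length(act) == 0L || length(base) < 2L) {
    stop("activation and baseline intervals must be non-empty", call. = FALSE)
  }
  mu <- mean(x[act])
  sigma <- stats::sd(x[base])
  if (sigma == 0) stop("zero baseline standard deviation", call. = FALSE)
  snr <- if (mu > 0) 20 * log10(mu / sigma) else NA_real_
  list(snr_db = snr, activation_mean = mu, baseline_sd = sigma)
}

#' SNR of an epoch set
#'
#' Convenience wrapper: SNR of each retained epoch, or of the retained-epoch
#' average.
#'
#' @param es An `epoch_set`.
#' @param average Compute on the retained-epoch average (`TRUE`, default) or
#'   per epoch.
#' @return `compute_snr()` result, or a list of results when `average=FALSE`.
#' @export
snr_of_epochs <- function(es, average = TRUE) {
  stopifnot(inherits(es, "epoch_set"))
  data <- es$data[es$retained, , drop = FALSE]
  if (nrow(data) == 0L) stop("no retained epochs", call. = FALSE)
  if (average) {
    compute_snr(colMeans(data), es$times, es$design$stim_s)
  } else {
    lapply(seq_len(nrow(data)), function(i) {
      compute_snr(data[i, ], es$times, es$design$stim_s)
    })
  }
}
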