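#' Sampling grid of a continuous recording
#'
#' fNIRS systems of the class targeted here sample hemoglobin concentration
#' changes on a fixed grid, typically at 10 Hz. All timing arithmetic in the
#' package goes through this object so that seconds-to-samples conversions use
#' one convention everywhere.
#'
#' @param dt Seconds per sample. Default 0.1 (10 Hz).
#' @param n_samples Number of samples in the recording.
#' @return An object of class `sampling_grid`.
#' @export
sampling_grid <- function(dt = 0.1, n_samples) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) {
    stop("`n_samples` must be >= 1", call. = FALSE)
  }
  structure(list(dt = dt, n_samples = n_samples), class = "sampling_grid")
}

#' Nearest-sample index for a time point
#'
#' Maps a time in seconds to the index of the nearest sample on the grid
#' (1-based, as usual in R; sample `i` sits at time `(i - 1) * dt`). Rounding
#' of half-way cases follows [round()], i.e. round-half-even, so the mapping
#' is deterministic and monotone non-decreasing in `t`.
#'
#' @param grid A [sampling_grid()].
#' @param t Time in seconds, `0 <= t <= (n_samples - 1) * dt`.
#' @return Integer sample index.
#' @export
time_index <- function(grid, t) {
  stopifnot(inherits(grid, "sampling_grid"))
  if (any(!is.finite(t)) || any(t < -1e-9) ||
      any(t > (grid$n_samples - 1L) * grid$dt + 1e-9)) {
    stop("time out of range of the sampling grid", call. = FALSE)
  }
  as.integer(round(t / grid$dt)) + 1L
}

#' Block-design timing of a session
#'
#' Describes the timing grammar of one block-design measurement: the number
#' of trials and the durations (seconds) of the prestimulus window (baseline
#' plus instruction), the baseline proper, the stimulus, and the poststimulus
#' window. `rest_s` is the inter-stimulus rest used when laying out a
#' simulated session; it does not affect epoching of measured data, where
#' trial onsets come from an events table.
#'
#' The defaults mirror a typical pediatric cognitive-task protocol: six
#' trials, 13 s prestimulus (10 s baseline + 3 s instruction), 24 s stimulus
#' and 13 s poststimulus, with 26 s rest between stimuli in simulation.
#'
#' @param n_trials Number of trials (epochs). Default 6.
#' @param pre_s Prestimulus duration in seconds. Default 13.
#' @param baseline_s Baseline duration in seconds (`<= pre_s`). Default 10.
#' @param stim_s Stimulus duration in seconds. Default 24.
#' @param post_s Poststimulus duration in seconds. Default 13.
#' @param rest_s Inter-stimulus rest for simulated sessions. Default 26.
#' @return An object of class `block_design`.
#' @export
block_design <- function(n_trials = 6L, pre_s = 13, baseline_s = 10,
                         stim_s = 24, post_s = 13, rest_s = 26) {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  durs <- c(pre_s = pre_s, baseline_s = baseline_s, stim_s = stim_s,
            post_s = post_s, rest_s = rest_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("all durations must be positive and finite", call. = FALSE)
  }
  if (baseline_s > pre_s) stop("`baseline_s` must not exceed `pre_s`", call. = FALSE)
  structure(list(n_trials = n_trials, pre_s = pre_s, baseline_s = baseline_s,
                 stim_s = stim_s, post_s = post_s, rest_s = rest_s),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("block design: %d trials; %.3g s pre (%.3g s baseline) + %.3g s stim + %.3g s post\n",
              x$n_trials, x$pre_s, x$baseline_s, x$stim_s, x$post_s))
  invisible(x)
}

epoch_length_s <- function(design) design$pre_s + design$stim_s + design$post_s

epoch_length_samples <- function(design, dt) as.integer(round(epoch_length_s(design) / dt))

#' Multichannel continuous recording
#'
#' One signal type (oxygenated, deoxygenated or total hemoglobin), one or more
#' channels, values in mM·mm on a uniform sampling grid, together with the
#' stimulus-onset times of the session's trials.
#'
#' @param values Numeric matrix (channels x samples) or a vector for a single
#'   channel.
#' @param dt Seconds per sample. Default 0.1.
#' @param channels Character vector of channel identifiers. Defaults to
#'   `"CH1"`, `"CH2"`, ...
#' @param signal_type One of `"O2Hb"`, `"HHb"`, `"HbTotal"`.
#' @param trial_onsets Stimulus-onset times in seconds from recording start.
#' @return An object of class `fnirs_recording`.
#' @export
continuous_recording <- function(values, dt = 0.1, channels = NULL,
                                 signal_type = c("O2Hb", "HHb", "HbTotal"),
                                 trial_onsets = numeric()) {
  signal_type <- match.arg(signal_type)
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("recording values must be finite", call. = FALSE)
  if (is.null(channels)) channels <- paste0("CH", seq_len(nrow(values)))
  if (length(channels) != nrow(values)) {
    stop("`channels` must name every row of `values`", call. = FALSE)
  }
  rownames(values) <- channels
  structure(list(grid = sampling_grid(dt, ncol(values)), channels = channels,
                 signal_type = signal_type, values = values,
                 trial_onsets = as.numeric(trial_onsets)),
            class = "fnirs_recording")
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("fNIRS recording: %d channel(s) x %d samples (%.1f s at %.3g Hz), %s, %d trial onset(s)\n",
              length(x$channels), x$grid$n_samples,
              x$grid$n_samples * x$grid$dt, 1 / x$grid$dt,
              x$signal_type, length(x$trial_onsets)))
  invisible(x)
}

#' Set of time-locked epochs for one channel
#'
#' Internal constructor assembling one channel's epochs into a matrix
#' (trials x samples) with a shared relative time axis running from
#' `-pre_s` up to (but excluding) `stim_s + post_s`.
#'
#' @noRd
new_epoch_set <- function(data, times, design, channel, signal_type, dt) {
  structure(list(data = data, times = times, design = design,
                 channel = channel, signal_type = signal_type, dt = dt,
                 retained = rep(TRUE, nrow(data))),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch set: %d epochs x %d samples, channel %s (%s), %d retained\n",
              nrow(x$data), ncol(x$data), x$channel, x$signal_type,
              sum(x$retained)))
  invisible(x)
}

#' Compartmentalize a continuous recording into epochs
#'
#' Cuts the recording into one time-locked segment per trial, the unit on
#' which noise identification, rejection and averaging operate. Windows are
#' half-open `[onset - pre_s, onset + stim_s + post_s)` in samples, with the
#' onset snapped to the nearest grid sample, so that contiguous windows never
#' share a sample.
#'
#' @param rec An [continuous_recording()].
#' @param design A [block_design()].
#' @param channel Channel id to extract; may be omitted when the recording
#'   has a single channel.
#' @return An object of class `epoch_set` with elements `data`
#'   (trials x samples matrix), `times` (seconds relative to stimulus onset),
#'   `design`, and a logical `retained` vector (all `TRUE` initially).
#' @export
extract_epochs <- function(rec, design, channel = NULL) {
  stopifnot(inherits(rec, "fnirs_recording"), inherits(design, "block_design"))
  if (is.null(channel)) {
    if (length(rec$channels) != 1L) {
      stop("recording has several channels; specify `channel`", call. = FALSE)
    }
    channel <- rec$channels[1L]
  }
  if (!channel %in% rec$channels) {
    stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  }
  onsets <- rec$trial_onsets
  if (length(onsets) == 0L) stop("recording has no trial onsets", call. = FALSE)
  dt <- rec$grid$dt
  len <- epoch_length_samples(design, dt)
  n <- rec$grid$n_samples
  x <- rec$values[channel, ]
  data <- matrix(NA_real_, nrow = length(onsets), ncol = len)
  for (i in seq_along(onsets)) {
    start_t <- onsets[i] - design$pre_s
    if (start_t < -1e-9) {
      stop(sprintf("trial %d: window starts before the recording", i), call. = FALSE)
    }
    i0 <- time_index(rec$grid, max(start_t, 0))
    if (i0 + len - 1L > n) {
      stop(sprintf("trial %d: window runs past the end of the recording", i), call. = FALSE)
    }
    data[i, ] <- x[i0:(i0 + len - 1L)]
  }
  times <- (seq_len(len) - 1L) * dt - design$pre_s
  new_epoch_set(data, times, design, channel, rec$signal_type, dt)
}

#' Build an epoch set from a trials-by-samples matrix
#'
#' For data epoched outside the package (or constructed directly in
#' analyses and tests): rows are trials, columns samples, and the time axis
#' is derived from the design, running from `-pre_s` in steps of `dt`. The
#' matrix must have exactly the design's epoch length in samples.
#'
#' @param data Numeric matrix, trials x samples.
#' @param design A [block_design()].
#' @param dt Seconds per sample. Default 0.1.
#' @param channel,signal_type Labels for the epochs.
#' @return An `epoch_set`.
#' @export
as_epoch_set <- function(data, design = block_design(), dt = 0.1,
                         channel = "CH1", signal_type = "O2Hb") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (trials x samples)", call. = FALSE)
  }
  len <- epoch_length_samples(design, dt)
  if (ncol(data) != len) {
    stop(sprintf("expected %d samples per epoch for this design, got %d",
                 len, ncol(data)), call. = FALSE)
  }
  times <- (seq_len(len) - 1L) * dt - design$pre_s
  new_epoch_set(data, times, design, channel, signal_type, dt)
}

#' Indices of the epoch time axis falling in a relative-time interval
#'
#' Half-open interval `[from, to)` in seconds relative to stimulus onset.
#' @noRd
epoch_window_idx <- function(times, from, to) {
  which(times >= from - 1e-9 & times < to - 1e-9)
}
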