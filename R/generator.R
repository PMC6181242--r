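#' Gamma hemodynamic response parameters
#'
#' The canonical single-gamma hemodynamic response function (HRF)
#' `h(t) = (t/tau)^(n-1) exp(-t/tau) / ((n-1)! tau)` with time constant
#' `tau = 1.08` s and shape `n = 3`, peaking at `tau * (n - 1) = 2.16` s.
#'
#' @param tau Time constant in seconds (> 0). Default 1.08.
#' @param n Integer shape (>= 1). Default 3.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(tau = 1.08, n = 3L) {
  n <- as.integer(n)
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (is.na(n) || n < 1L) stop("`n` must be an integer >= 1", call. = FALSE)
  structure(list(tau = tau, n = n), class = "hrf_params")
}

#' Gamma hemodynamic response function
#'
#' Evaluates the gamma HRF at times `t` (seconds). Negative times map to 0.
#' The function is a gamma probability density, so it is nonnegative, has a
#' single interior maximum at `tau * (n - 1)`, and integrates to one.
#'
#' @param t Numeric vector of times in seconds.
#' @param params An [hrf_params()].
#' @return Numeric vector `h(t)`.
#' @export
gamma_hrf <- function(t, params = hrf_params()) {
  stopifnot(inherits(params, "hrf_params"))
  h <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos] / params$tau
  h[pos] <- tp^(params$n - 1L) * exp(-tp) / (gamma(params$n) * params$tau)
  h
}

#' First derivative of the gamma HRF, with a non-recovery variant
#'
#' The analytic derivative `h'(t)` is the kernel used to shape spike
#' artifacts: convolving a short rebound step with `h'` gives a transient
#' that returns to the pre-spike level (a recovered spike). The
#' non-recovery variant keeps `h'` unchanged up to its maximum and replaces
#' it by `2 h'(t) - max h'` afterwards; since `h'` decays to zero, the
#' modified kernel settles at `-max h'`, so the convolved artifact never
#' returns to its starting level.
#'
#' @param t Numeric vector of times in seconds.
#' @param params An [hrf_params()].
#' @param recover If `FALSE`, return the non-recovery variant.
#' @return Numeric vector.
#' @export
gamma_hrf_deriv <- function(t, params = hrf_params(), recover = TRUE) {
  stopifnot(inherits(params, "hrf_params"))
  d <- numeric(length(t))
  pos <- t > 0
  h <- gamma_hrf(t[pos], params)
  d[pos] <- h * ((params$n - 1L) / t[pos] - 1 / params$tau)
  if (!recover) {
    # argmax of h' sits at tau * (n - 2) for n > 2; locate it on the grid
    # so the splice point is exact for arbitrary shapes.
    imax <- which.max(d)
    m <- d[imax]
    after <- seq_along(d) > imax
    d[after] <- 2 * d[after] - m
  }
  d
}

#' Boxcar (stimulus response amplitude) parameters
#'
#' The task-evoked response is modeled as a boxcar at the stimulus intervals
#' convolved with the HRF. The boxcar amplitude is Gaussian with mean
#' `mean_amp` and standard deviation `sd_amp`; `ratio = mean_amp / sd_amp`
#' may be given instead of `sd_amp`. `amp_per` selects whether one amplitude
#' is drawn per recording (between-signal response variability, the default)
#' or independently per trial.
#'
#' @param mean_amp Mean amplitude, arbitrary concentration units (typical
#'   range 0.14 to 0.3). Default 0.2.
#' @param sd_amp Amplitude standard deviation (>= 0). Default 0.
#' @param ratio Optional mean/SD ratio; when given, `sd_amp = mean_amp/ratio`.
#' @param amp_per `"recording"` (default) or `"trial"`.
#' @return An object of class `boxcar_params`.
#' @export
boxcar_params <- function(mean_amp = 0.2, sd_amp = 0, ratio = NULL,
                          amp_per = c("recording", "trial")) {
  amp_per <- match.arg(amp_per)
  if (!is.finite(mean_amp) || mean_amp < 0) {
    stop("`mean_amp` must be nonnegative", call. = FALSE)
  }
  if (!is.null(ratio)) {
    if (!is.finite(ratio) || ratio <= 0) stop("`ratio` must be positive", call. = FALSE)
    sd_amp <- mean_amp / ratio
  }
  if (!is.finite(sd_amp) || sd_amp < 0) stop("`sd_amp` must be nonnegative", call. = FALSE)
  structure(list(mean_amp = mean_amp, sd_amp = sd_amp, amp_per = amp_per),
            class = "boxcar_params")
}

#' Synthetic noise-model parameters
#'
#' Configuration of the artifact and noise components of the generator:
#' spikes (recovered and non-recovery) shaped by the HRF derivative with peak
#' magnitudes drawn uniformly from `spike_peak_range` and random sign;
#' prestimulus baseline shifts with Gaussian slope (mean
#' `shift_slope_mean`, SD `shift_slope_sd`, random sign); band-limited
#' Gaussian physiological noise (`phys_sd`, 4th-order Butterworth band
#' `phys_band`); and white Gaussian machine noise calibrated so the
#' activation-to-baseline SNR equals `snr_db`.
#'
#' @param spike_peak_range Range of spike peak magnitudes (mM·mm).
#'   Default `c(0.14, 0.48)`.
#' @param spike_width_s Width of the rebound step convolved with the HRF
#'   derivative, seconds. Default 1.
#' @param shift_slope_mean Mean baseline-shift slope, mM·mm/s. Default 0.025.
#' @param shift_slope_sd SD of the baseline-shift slope (range 0 to 0.025).
#'   Default 0.0125.
#' @param max_noise_events Maximum number of injected events (at most one
#'   per trial). Default 6.
#' @param phys_sd SD of the physiological noise before band-limiting.
#'   Default 1/6.
#' @param phys_band Physiological band in Hz. Default `c(0.08, 0.15)`.
#' @param snr_db Target signal-to-noise ratio in dB (machine-noise
#'   calibration). Default 0.
#' @param machine_ref_amp Activation amplitude used as the SNR reference;
#'   defaults to the boxcar mean amplitude.
#' @return An object of class `noise_model_params`.
#' @export
noise_model_params <- function(spike_peak_range = c(0.14, 0.48),
                               spike_width_s = 1,
                               shift_slope_mean = 0.025,
                               shift_slope_sd = 0.0125,
                               max_noise_events = 6L,
                               phys_sd = 1 / 6,
                               phys_band = c(0.08, 0.15),
                               snr_db = 0,
                               machine_ref_amp = NULL) {
  if (any(spike_peak_range <= 0) || diff(spike_peak_range) < 0) {
    stop("`spike_peak_range` must be positive and increasing", call. = FALSE)
  }
  if (!is.finite(snr_db)) stop("`snr_db` must be finite", call. = FALSE)
  if (phys_sd < 0) stop("`phys_sd` must be nonnegative", call. = FALSE)
  structure(list(spike_peak_range = spike_peak_range,
                 spike_width_s = spike_width_s,
                 shift_slope_mean = shift_slope_mean,
                 shift_slope_sd = shift_slope_sd,
                 max_noise_events = as.integer(max_noise_events),
                 phys_sd = phys_sd, phys_band = phys_band,
                 snr_db = snr_db, machine_ref_amp = machine_ref_amp),
            class = "noise_model_params")
}

# Discrete HRF kernel normalized to unit area (sum * dt = 1) so that
# convolution with a boxcar of amplitude A plateaus exactly at A.
hrf_kernel <- function(dt, params, dur_s = 6 * params$tau * params$n) {
  tk <- seq(0, dur_s, by = dt)
  k <- gamma_hrf(tk, params)
  k / (sum(k) * dt)
}

# Layout of a simulated session: first onset after one rest interval,
# subsequent onsets spaced stim + rest.
session_layout <- function(design, dt) {
  onsets <- design$rest_s + (seq_len(design$n_trials) - 1L) * (design$stim_s + design$rest_s)
  total_s <- design$rest_s + design$n_trials * (design$stim_s + design$rest_s)
  n <- as.integer(round(total_s / dt))
  list(onsets = onsets, n = n, t = (seq_len(n) - 1L) * dt)
}

#' Task-related hemodynamic signal
#'
#' Draws boxcar amplitudes (see [boxcar_params()]), builds the stimulus
#' boxcar of the session, and convolves it with the unit-area HRF kernel, so
#' each trial's response plateau equals its drawn amplitude. Uses the current
#' RNG stream; seed upstream for reproducibility.
#'
#' @param design A [block_design()].
#' @param box A [boxcar_params()].
#' @param hrf An [hrf_params()].
#' @param dt Seconds per sample. Default 0.1.
#' @return List with `signal` (numeric vector), `amplitudes` (one per
#'   trial), `onsets` (seconds) and `n` (samples).
#' @export
task_response <- function(design = block_design(), box = boxcar_params(),
                          hrf = hrf_params(), dt = 0.1) {
  stopifnot(inherits(design, "block_design"), inherits(box, "boxcar_params"))
  lay <- session_layout(design, dt)
  amps <- if (box$amp_per == "recording") {
    rep(stats::rnorm(1L, box$mean_amp, box$sd_amp), design$n_trials)
  } else {
    stats::rnorm(design$n_trials, box$mean_amp, box$sd_amp)
  }
  boxcar <- numeric(lay$n)
  for (i in seq_len(design$n_trials)) {
    idx <- which(lay$t >= lay$onsets[i] - 1e-9 &
                   lay$t < lay$onsets[i] + design$stim_s - 1e-9)
    boxcar[idx] <- amps[i]
  }
  k <- hrf_kernel(dt, hrf)
  sig <- convolve_causal(boxcar, k * dt)
  list(signal = sig, amplitudes = amps, onsets = lay$onsets, n = lay$n)
}

# Causal linear convolution truncated to the length of x.
convolve_causal <- function(x, k) {
  y <- stats::convolve(x, rev(k), type = "open")
  y[seq_along(x)]
}

#' Band-limited Gaussian physiological noise
#'
#' Zero-mean Gaussian noise with standard deviation `sd`, band-pass filtered
#' with a Butterworth response of the given order, emulating spontaneous
#' low-frequency hemodynamic oscillations (Mayer-wave band by default).
#'
#' @param n Number of samples.
#' @param dt Seconds per sample.
#' @param sd Pre-filter standard deviation. Default 1/6.
#' @param band Band edges in Hz. Default `c(0.08, 0.15)`.
#' @param order Butterworth design order. Default 4.
#' @return Numeric vector of length `n`.
#' @export
physiological_noise <- function(n, dt = 0.1, sd = 1 / 6,
                                band = c(0.08, 0.15), order = 4L) {
  if (sd == 0) return(numeric(n))
  bandpass_series(stats::rnorm(n, 0, sd), dt, band[1L], band[2L], order = order)
}

#' Machine-noise standard deviation for a target SNR
#'
#' Inverts the decibel SNR definition
#' `SNR = 20 log10(activation_mean / baseline_sd)`:
#' `sigma = activation_mean / 10^(snr_db / 20)`.
#'
#' @param snr_db Target SNR in dB.
#' @param activation_mean Reference activation amplitude (> 0).
#' @return Standard deviation of the white machine noise.
#' @export
machine_noise_sigma <- function(snr_db, activation_mean) {
  if (!is.finite(snr_db)) stop("`snr_db` must be finite", call. = FALSE)
  if (!is.finite(activation_mean) || activation_mean <= 0) {
    stop("`activation_mean` must be positive", call. = FALSE)
  }
  activation_mean / 10^(snr_db / 20)
}

#' White Gaussian machine noise at a target SNR
#'
#' @param n Number of samples.
#' @param snr_db Target SNR in dB.
#' @param activation_mean Reference activation amplitude (> 0).
#' @return Numeric vector of length `n`.
#' @export
machine_noise <- function(n, snr_db, activation_mean) {
  stats::rnorm(n, 0, machine_noise_sigma(snr_db, activation_mean))
}

# Spike artifact waveform: rebound step convolved with the HRF derivative
# (recovered) or its non-recovery variant, rescaled so the extremum equals
# peak, with the requested sign.
spike_waveform <- function(dt, hrf, peak, sign, recover, width_s, dur_s) {
  tk <- seq(0, dur_s, by = dt)
  kern <- gamma_hrf_deriv(tk, hrf, recover = recover)
  step <- rep(1, max(1L, as.integer(round(width_s / dt))))
  w <- convolve_causal(c(kern, numeric(length(step))), step * dt)
  w <- w[seq_len(length(tk))]
  w / max(abs(w)) * peak * sign
}

#' Generate a synthetic block-design fNIRS recording
#'
#' Builds an artificial recording `f(t) = h*b + p + m`, i.e. the task-related
#' response (HRF convolved with the session boxcar) plus band-limited
#' physiological noise plus SNR-calibrated machine noise, optionally with
#' injected artifact events. Events are placed in distinct, randomly chosen
#' trials (at most `max_noise_events`); each event is a baseline shift with
#' probability 1/2 or a spike (recovered or non-recovery, equally likely)
#' otherwise. Spikes are placed uniformly inside the trial's epoch window at
#' least 2 s from its edges; baseline shifts ramp across the 13-s prestimulus
#' and hold their offset until the end of the trial's window. Every injected
#' event is returned in the ground-truth annotation.
#'
#' @param design A [block_design()].
#' @param box A [boxcar_params()].
#' @param hrf An [hrf_params()].
#' @param noise A [noise_model_params()].
#' @param with_noise Inject artifact events? Default `FALSE`.
#' @param n_events Number of events to inject (overrides the random draw of
#'   1 to `max_noise_events`).
#' @param dt Seconds per sample. Default 0.1.
#' @param seed Optional integer seed; when given the output is a
#'   deterministic function of the arguments.
#' @return A list of class `synthetic_recording` with elements `recording`
#'   (an [continuous_recording()]), `ground_truth` (list with `events`
#'   data frame and logical `clean` per trial), `task` (the clean
#'   task-related component), and `amplitudes`.
#' @export
generate_recording <- function(design = block_design(), box = boxcar_params(),
                               hrf = hrf_params(),
                               noise = noise_model_params(),
                               with_noise = FALSE, n_events = NULL,
                               dt = 0.1, seed = NULL) {
  stopifnot(inherits(noise, "noise_model_params"))
  if (!is.null(seed)) set.seed(seed)
  tr <- task_response(design, box, hrf, dt)
  n <- tr$n
  p <- physiological_noise(n, dt, noise$phys_sd, noise$phys_band)
  ref <- if (!is.null(noise$machine_ref_amp)) noise$machine_ref_amp else box$mean_amp
  m <- machine_noise(n, noise$snr_db, ref)
  artifact <- numeric(n)
  events <- data.frame(trial = integer(), type = character(),
                       time_s = numeric(), magnitude = numeric(),
                       stringsAsFactors = FALSE)
  if (with_noise) {
    max_ev <- min(noise$max_noise_events, design$n_trials)
    ne <- if (is.null(n_events)) sample.int(max_ev, 1L) else as.integer(n_events)
    if (ne > design$n_trials) stop("more events than trials", call. = FALSE)
    if (ne > 0L) {
      trials <- sort(sample.int(design$n_trials, ne))
      for (tr_i in trials) {
        onset <- tr$onsets[tr_i]
        win_start <- onset - design$pre_s
        win_end <- onset + design$stim_s + design$post_s
        type <- sample(c("spike", "nonrecovery_spike", "baseline_shift"),
                       1L, prob = c(0.25, 0.25, 0.5))
        if (type == "baseline_shift") {
          # slope added over the prestimulus (baseline) interval only: the
          # epoch's baseline drifts away from its surroundings
          slope <- stats::rnorm(1L, noise$shift_slope_mean, noise$shift_slope_sd)
          sgn <- sample(c(-1, 1), 1L)
          i0 <- as.integer(round(win_start / dt)) + 1L
          i1 <- as.integer(round(onset / dt))
          idx_all <- i0:i1
          t_rel <- ((idx_all - 1L) * dt) - win_start
          artifact[idx_all] <- artifact[idx_all] + t_rel * slope * sgn
          events <- rbind(events, data.frame(
            trial = tr_i, type = type, time_s = win_start,
            magnitude = slope * sgn, stringsAsFactors = FALSE))
        } else {
          t_ev <- stats::runif(1L, win_start + 2, win_end - 2)
          peak <- stats::runif(1L, noise$spike_peak_range[1L],
                               noise$spike_peak_range[2L])
          sgn <- sample(c(-1, 1), 1L)
          i_ev <- as.integer(round(t_ev / dt)) + 1L
          dur_s <- win_end - t_ev
          w <- spike_waveform(dt, hrf, peak, sgn,
                              recover = (type == "spike"),
                              width_s = noise$spike_width_s, dur_s = dur_s)
          idx <- i_ev:min(n, i_ev + length(w) - 1L)
          i_stop <- as.integer(round(win_end / dt))
          idx <- idx[idx <= i_stop]
          artifact[idx] <- artifact[idx] + w[seq_along(idx)]
          events <- rbind(events, data.frame(
            trial = tr_i, type = type, time_s = t_ev,
            magnitude = peak * sgn, stringsAsFactors = FALSE))
        }
      }
    }
  }
  clean <- !(seq_len(design$n_trials) %in% events$trial)
  rec <- continuous_recording(tr$signal + p + m + artifact, dt = dt,
                              channels = "CH1", signal_type = "O2Hb",
                              trial_onsets = tr$onsets)
  structure(list(recording = rec,
                 ground_truth = list(events = events, clean = clean),
                 task = tr$signal, amplitudes = tr$amplitudes,
                 design = design),
            class = "synthetic_recording")
}
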