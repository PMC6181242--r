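test_that("gamma HRF has the analytic shape", {
  p <- hrf_params()
  expect_identical(gamma_hrf(0, p), 0)
  # dense-grid argmax sits at tau * (n - 1) = 2.16 s
  tt <- seq(0, 20, by = 1e-3)
  h <- gamma_hrf(tt, p)
  expect_equal(tt[which.max(h)], 2.16, tolerance = 1e-3)
  # direct evaluation at the peak: 2^2 e^-2 / (2! * 1.08)
  expect_equal(gamma_hrf(2.16, p), 4 * exp(-2) / (2 * 1.08), tolerance = 1e-12)
  expect_true(all(h >= 0))
  # single interior maximum: one sign change of the discrete difference
  expect_identical(sum(diff(sign(diff(h))) != 0), 1L)
  expect_error(hrf_params(tau = -1), "positive")
  expect_error(hrf_params(n = 0), ">= 1")
})

test_that("HRF derivative kernels splice and settle as constructed", {
  p <- hrf_params()
  tt <- seq(0, 40, by = 0.01)
  d <- gamma_hrf_deriv(tt, p)
  dn <- gamma_hrf_deriv(tt, p, recover = FALSE)
  imax <- which.max(d)
  # unchanged up to and including the maximum (2*max - max = max there)
  expect_identical(dn[1:imax], d[1:imax])
  # the non-recovery tail settles at -max h' since h' decays to zero
  expect_equal(tail(dn, 1), -max(d), tolerance = 1e-6)
  # integral of the unmodified derivative over [0, inf) is h(inf)-h(0) = 0
  expect_equal(sum(d) * 0.01, 0, tolerance = 1e-4)
})

test_that("task response plateaus at the drawn amplitude", {
  d <- block_design()
  set.seed(1)
  tr <- task_response(d, boxcar_params(mean_amp = 0.2, sd_amp = 0))
  t <- (seq_len(tr$n) - 1L) * 0.1
  peaks <- vapply(tr$onsets, function(on) {
    max(tr$signal[t >= on & t < on + d$stim_s])
  }, numeric(1L))
  expect_equal(peaks, rep(0.2, 6L), tolerance = 0.004)  # within 2 %
  # zero mean amplitude gives the zero signal
  set.seed(1)
  expect_true(all(task_response(d, boxcar_params(mean_amp = 0))$signal == 0))
  # per-trial draws: each trial's peak tracks its own amplitude
  set.seed(2)
  tr2 <- task_response(d, boxcar_params(0.2, 0.05, amp_per = "trial"))
  peaks2 <- vapply(seq_along(tr2$onsets), function(i) {
    on <- tr2$onsets[i]
    max(tr2$signal[t >= on & t < on + d$stim_s])
  }, numeric(1L))
  expect_equal(peaks2, tr2$amplitudes, tolerance = 0.02)
})

test_that("physiological noise is band-limited, zero-mean and seeded", {
  set.seed(10)
  x <- physiological_noise(1e5, dt = 0.1)
  expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)) + 1e-3)
  sp <- spec.pgram(ts(x, frequency = 10), plot = FALSE, taper = 0)
  pw <- function(f) mean(sp$spec[abs(sp$freq - f) < 0.01])
  expect_lt(pw(0.4) / pw(0.115), 0.01)
  set.seed(42); a <- physiological_noise(500)
  set.seed(42); b <- physiological_noise(500)
  expect_identical(a, b)
})

test_that("machine noise sigma inverts the decibel SNR definition", {
  expect_equal(machine_noise_sigma(0, 0.2), 0.2)
  expect_equal(machine_noise_sigma(20, 0.2), 0.02)
  expect_equal(machine_noise_sigma(-40, 0.2), 20)
  expect_error(machine_noise_sigma(NA, 0.2), "finite")
  expect_error(machine_noise_sigma(0, 0), "positive")
  set.seed(3)
  expect_equal(sd(machine_noise(2e4, 0, 0.2)), 0.2, tolerance = 0.01)
})

test_that("generated recordings are deterministic given a seed", {
  a <- generate_recording(with_noise = TRUE, seed = 11L)
  b <- generate_recording(with_noise = TRUE, seed = 11L)
  expect_identical(a$recording$values, b$recording$values)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("ground truth annotates exactly the injected trials", {
  clean <- generate_recording(with_noise = FALSE, seed = 5L)
  expect_identical(nrow(clean$ground_truth$events), 0L)
  expect_true(all(clean$ground_truth$clean))
  full <- generate_recording(with_noise = TRUE, n_events = 6L, seed = 5L)
  expect_identical(nrow(full$ground_truth$events), 6L)
  expect_true(all(!full$ground_truth$clean))
  # every event lies inside its trial's epoch window
  d <- full$design
  onsets <- full$recording$trial_onsets
  ev <- full$ground_truth$events
  for (k in seq_len(nrow(ev))) {
    on <- onsets[ev$trial[k]]
    expect_gte(ev$time_s[k], on - d$pre_s)
    expect_lt(ev$time_s[k], on + d$stim_s + d$post_s)
  }
})

test_that("trials without events carry only task + noise components", {
  syn <- generate_recording(box = boxcar_params(0.2, 0),
                            noise = noise_model_params(snr_db = 60,
                                                       phys_sd = 0),
                            with_noise = TRUE, n_events = 2L, seed = 9L)
  clean_syn <- generate_recording(box = boxcar_params(0.2, 0),
                                  noise = noise_model_params(snr_db = 60,
                                                             phys_sd = 0),
                                  with_noise = FALSE, seed = 9L)
  d <- syn$design
  es <- extract_epochs(syn$recording, d)
  es_clean <- extract_epochs(clean_syn$recording, d)
  for (tr in which(syn$ground_truth$clean)) {
    expect_equal(es$data[tr, ], es_clean$data[tr, ], tolerance = 1e-3)
  }
})

test_that("injected baseline shifts are recoverable from the raw prestimulus", {
  found <- 0L
  for (s in 1:40) {
    syn <- generate_recording(box = boxcar_params(0.2, 0),
                              noise = noise_model_params(snr_db = 60, phys_sd = 0,
                                                         shift_slope_sd = 0),
                              with_noise = TRUE, n_events = 6L, seed = 100L + s)
    ev <- syn$ground_truth$events
    shifts <- ev[ev$type == "baseline_shift", ]
    if (nrow(shifts) == 0L) next
    d <- syn$design
    es <- extract_epochs(syn$recording, d)
    for (k in seq_len(nrow(shifts))) {
      tr <- shifts$trial[k]
      idx <- which(es$times < 0)
      t <- es$times[idx]; y <- es$data[tr, idx]
      slope <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
      expect_equal(slope, shifts$magnitude[k], tolerance = abs(shifts$magnitude[k]) * 0.2)
      found <- found + 1L
    }
    if (found >= 5L) break
  }
  expect_gte(found, 5L)
})

test_that("requested SNR is recovered from raw epochs within 1 dB", {
  for (snr in c(-20, 0, 20)) {
    mus <- c(); sds <- c()
    for (s in 1:10) {
      syn <- generate_recording(box = boxcar_params(0.2, 0),
                                noise = noise_model_params(snr_db = snr,
                                                           phys_sd = 0),
                                seed = 1000L * s + snr)
      es <- extract_epochs(syn$recording, syn$design)
      per <- snr_of_epochs(es, average = FALSE)
      mus <- c(mus, vapply(per, `[[`, numeric(1L), "activation_mean"))
      sds <- c(sds, vapply(per, `[[`, numeric(1L), "baseline_sd"))
    }
    measured <- 20 * log10(mean(mus) / mean(sds))
    expect_lt(abs(measured - snr), 1)
  }
})
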