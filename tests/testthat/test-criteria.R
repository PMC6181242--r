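# The detector oracles (oracle_jump, oracle_corr_flags) live in
# helper-synthetic.R and are shared with the acceptance suite.


test_that("sustained steps are flagged, recovering spikes are not", {
  d <- block_design()
  len <- 500L
  step <- numeric(len); step[200:len] <- 0.5
  fl <- detect_amplitude_jump(step, 0.1, criterion1_config())
  expect_identical(nrow(fl), 1L)
  expect_equal(fl$severity, 0.5, tolerance = 1e-9)
  spike <- numeric(len); spike[200] <- 0.5   # up and back within 0.3 s
  expect_identical(nrow(detect_amplitude_jump(spike, 0.1, criterion1_config())), 0L)
  flat <- numeric(len)
  expect_identical(nrow(detect_amplitude_jump(flat, 0.1, criterion1_config())), 0L)
})

test_that("edge-truncated base windows warn and still decide", {
  x <- numeric(100L); x[3:100] <- 0.5
  expect_warning(fl <- detect_amplitude_jump(x, 0.1, criterion1_config()),
                 "truncated")
  expect_identical(nrow(fl), 1L)
})

test_that("jump detector agrees with a brute-force oracle on random epochs", {
  set.seed(101)
  mismatches <- 0L
  for (r in 1:500) {
    x <- rnorm(100, sd = 0.05)
    if (r %% 3 == 0) {                 # plant a step artifact sometimes
      at <- sample(20:80, 1L)
      x[at:100] <- x[at:100] + runif(1, 0.1, 0.6) * sample(c(-1, 1), 1L)
    }
    cfg <- criterion1_config(jump_threshold = runif(1, 0.05, 0.2),
                             recovery_threshold = runif(1, 0.05, 0.3))
    got <- suppressWarnings(detect_amplitude_jump(x, 0.1, cfg))
    want <- suppressWarnings(
      oracle_jump(x, 0.1, cfg$jump_threshold, 1, cfg$recovery_threshold))
    same <- if (is.null(want)) nrow(got) == 0L else {
      nrow(got) == 1L && isTRUE(all.equal(got$severity, want))
    }
    mismatches <- mismatches + !same
  }
  expect_identical(mismatches, 0L)
})

test_that("baseline drift thresholds the absolute least-squares slope", {
  d <- block_design()
  times <- (seq_len(500L) - 1L) * 0.1 - 13
  ramp <- ifelse(times < 0, 0.05 * (times + 13), 0.05 * 13)
  fl <- detect_baseline_drift(ramp, times, 13, criterion2_config(0.029))
  expect_identical(nrow(fl), 1L)
  expect_equal(fl$severity, 0.05, tolerance = 1e-9)
  # negative slopes count through the absolute value
  fl2 <- detect_baseline_drift(-ramp, times, 13, criterion2_config(0.029))
  expect_identical(nrow(fl2), 1L)
  expect_identical(nrow(detect_baseline_drift(numeric(500L), times, 13,
                                              criterion2_config())), 0L)
})

test_that("noisy slopes are recovered near the closed form and decided consistently", {
  times <- (seq_len(500L) - 1L) * 0.1 - 13
  pre <- times < 0
  t <- times[pre]
  set.seed(55)
  for (r in 1:50) {
    a <- runif(1, 0, 0.06)
    x <- numeric(500L)
    x[pre] <- a * (t + 13) + rnorm(sum(pre), 0, 0.01)
    y <- x[pre]
    slope_hat <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    se <- sqrt(sum((y - mean(y) - slope_hat * (t - mean(t)))^2) /
                 (sum(pre) - 2) / sum((t - mean(t))^2))
    expect_lt(abs(slope_hat - a), 4 * se + 1e-6)
    fl <- detect_baseline_drift(x, times, 13, criterion2_config(0.029))
    expect_identical(nrow(fl) == 1L, abs(slope_hat) > 0.029)
  }
})

test_that("correlation criterion reproduces hand-computed degenerate cases", {
  d <- block_design()
  len <- as.integer((13 + 24 + 13) / 0.1)
  base <- sin(2 * pi * (seq_len(len)) / 120)
  same6 <- as_epoch_set(matrix(rep(base, 6), nrow = 6, byrow = TRUE), d)
  # all sums equal 5, IQR 0, fence 5: strict < flags nothing
  expect_identical(nrow(detect_low_correlation(same6, 1:6, criterion3_config(0.6))), 0L)
  flip <- as_epoch_set(rbind(matrix(rep(base, 5), nrow = 5, byrow = TRUE),
                             -base), d)
  fl <- detect_low_correlation(flip, 1:6, criterion3_config(0.6))
  # identical epochs sum to 4 - 1 = 3, the flipped one to -5; fence = 3
  expect_identical(fl$epoch, 6L)
  expect_equal(fl$severity, 3 - (-5), tolerance = 1e-9)
})

test_that("correlation criterion is invariant to epoch ordering", {
  d <- block_design()
  set.seed(77)
  data <- random_epochs(6L, d)
  data[4L, ] <- -rowMeans(data[-4L, ])    # make one clear outlier
  es <- as_epoch_set(data, d)
  fl <- detect_low_correlation(es, 1:6, criterion3_config(0.6))
  perm <- sample(6L)
  es_p <- as_epoch_set(data[perm, ], d)
  fl_p <- detect_low_correlation(es_p, 1:6, criterion3_config(0.6))
  expect_setequal(perm[fl_p$epoch], fl$epoch)
})

test_that("correlation flags agree with a brute-force oracle on random sets", {
  d <- block_design()
  set.seed(303)
  for (r in 1:500) {
    n_ep <- sample(3:8, 1L)
    data <- random_epochs(n_ep, d)
    if (r %% 2 == 0) data[sample(n_ep, 1L), ] <- data[sample(n_ep, 1L), ] * -1
    if (r %% 7 == 0) data[sample(n_ep, 1L), ] <- 0   # zero-variance epoch
    k <- runif(1, 0, 2)
    es <- as_epoch_set(data, d)
    got <- detect_low_correlation(es, seq_len(n_ep), criterion3_config(k))
    expect_identical(got$epoch, oracle_corr_flags(data, k),
                     label = sprintf("case %d", r))
  }
})

test_that("criterion 3 skips with fewer than three retained epochs", {
  d <- block_design()
  es <- as_epoch_set(random_epochs(6L, d), d)
  expect_message(fl <- detect_low_correlation(es, 1:2, criterion3_config()),
                 "skipped")
  expect_identical(nrow(fl), 0L)
})

test_that("flag sets are nested along threshold sweeps", {
  d <- block_design()
  set.seed(404)
  es <- as_epoch_set(random_epochs(6L, d, sd = 0.15), d)
  flags_at <- function(cfg) noise_flags(es, cfg)$epoch
  prev <- integer(0L)
  for (thr in c(0.5, 0.3, 0.2, 0.1, 0.05)) {  # lower jump threshold: more flags
    cur <- suppressWarnings(
      flags_at(criterion1_config(jump_threshold = thr,
                                 recovery_threshold = 0.05)))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  prev <- integer(0L)
  for (thr in c(0.1, 0.05, 0.02, 0.01)) {
    cur <- flags_at(criterion2_config(slope_threshold = thr))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  prev <- integer(0L)
  for (k in c(2, 1, 0.5, 0)) {                 # k -> 0 raises the fence
    cur <- flags_at(criterion3_config(k_iqr = k))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})
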