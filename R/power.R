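#' Activation value of each retained epoch
#'
#' The activation value of an epoch is its mean amplitude over the
#' activation interval, 4 s after stimulus onset to the end of the stimulus,
#' computed after baseline normalization.
#'
#' @param es A baseline-normalized `epoch_set`.
#' @return Data frame with columns `epoch` and `activation` (mM·mm), one row
#'   per retained epoch.
#' @export
epoch_activation <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  idx <- epoch_window_idx(es$times, 4, es$design$stim_s)
  keep <- which(es$retained)
  if (length(keep) == 0L) stop("no retained epochs", call. = FALSE)
  data.frame(epoch = keep,
             activation = rowMeans(es$data[keep, idx, drop = FALSE]))
}

#' One-sample t-test of activation values
#'
#' Tests the epoch activation values against zero; the default is the
#' one-tailed test for positive activation. Zero-variance inputs are
#' degenerate: the t statistic is undefined and the result is flagged
#' rather than fabricated.
#'
#' @param values Numeric activation values (length >= 2).
#' @param alpha Significance level. Default 0.05.
#' @param alternative `"greater"` (default, positive activation) or
#'   `"two.sided"`.
#' @return List with `statistic`, `p_value`, `df`, `significant`,
#'   `degenerate`.
#' @export
activation_ttest <- function(values, alpha = 0.05,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                df = length(values) - 1L, significant = NA,
                degenerate = TRUE))
  }
  tt <- stats::t.test(values, mu = 0, alternative = alternative)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), significant = tt$p.value < alpha,
       degenerate = FALSE)
}

# Derive a per-simulation seed from the top-level seed so that cells of a
# simulation grid are paired (common random numbers across cells).
derive_seed <- function(seed, i) {
  # double arithmetic keeps intermediates exact; result fits in 32 bits
  s <- (as.numeric(seed) %% 100003) * 20011 + as.numeric(i) * 7919
  as.integer(s %% 2147483629)
}

simulate_activation_test <- function(design, box, hrf, noise, with_noise,
                                     n_reject, alpha, config, sim_seed) {
  set.seed(sim_seed)
  syn <- generate_recording(design, box, hrf, noise, with_noise = with_noise)
  rec <- preprocess(syn$recording, config)
  es <- extract_epochs(rec, design)
  if (n_reject > 0L) {
    drop <- sample.int(design$n_trials, n_reject)
    es$retained[drop] <- FALSE
  }
  es <- normalize_baseline(es)
  act <- epoch_activation(es)$activation
  tt <- activation_ttest(act, alpha = alpha)
  isTRUE(tt$significant)
}

#' Statistical power of epoch averaging under random rejection
#'
#' For every combination of activation mean/SD ratio, SNR and random
#' rejection count, simulates `n_sims` synthetic recordings, preprocesses
#' and epochs them, randomly drops the stated number of epochs, tests the
#' remaining activation values with a one-tailed one-sample t-test, and
#' reports the fraction of significant outcomes. Simulations are paired
#' across cells (common random numbers driven by `seed`), which makes
#' power differences between cells far less noisy than the marginal
#' binomial error.
#'
#' @param ratios Activation mean/SD ratios (`Inf` for a deterministic
#'   amplitude). Default `c(0.85, 1, 2)`.
#' @param snr_dbs SNR grid in dB. Default `seq(-40, 20, 2)`.
#' @param n_rejects Random rejection counts. Default `0:4`.
#' @param with_noise Simulate with injected artifact events? Default `FALSE`.
#' @param n_sims Simulations per cell.
#' @param design A [block_design()].
#' @param hrf An [hrf_params()].
#' @param mean_amp Boxcar mean amplitude. Default 0.2. Use `0` with
#'   `machine_ref_amp` for null (type-I error) simulations.
#' @param machine_ref_amp SNR reference amplitude when `mean_amp` is not
#'   positive.
#' @param alpha Significance level of the one-tailed test. Default 0.05.
#' @param config A [preprocess_config()].
#' @param seed Integer seed driving all randomness.
#' @return Data frame with one row per cell: `ratio`, `snr_db`,
#'   `n_rejected`, `with_noise`, `power`, `n_sims`.
#' @export
power_simulation <- function(ratios = c(0.85, 1, 2),
                             snr_dbs = seq(-40, 20, by = 2),
                             n_rejects = 0:4,
                             with_noise = FALSE,
                             n_sims = 1000L,
                             design = block_design(),
                             hrf = hrf_params(),
                             mean_amp = 0.2,
                             machine_ref_amp = NULL,
                             alpha = 0.05,
                             config = preprocess_config(),
                             seed = 1L) {
  stopifnot(n_sims >= 1L)
  cells <- expand.grid(ratio = ratios, snr_db = snr_dbs,
                       n_rejected = n_rejects, with_noise = with_noise,
                       KEEP.OUT.ATTRS = FALSE)
  cells$power <- NA_real_
  cells$n_sims <- as.integer(n_sims)
  for (ci in seq_len(nrow(cells))) {
    ratio <- cells$ratio[ci]
    box <- if (mean_amp > 0 && is.finite(ratio)) {
      boxcar_params(mean_amp = mean_amp, ratio = ratio)
    } else {
      boxcar_params(mean_amp = mean_amp, sd_amp = 0)
    }
    noise <- noise_model_params(snr_db = cells$snr_db[ci],
                                machine_ref_amp = machine_ref_amp)
    hits <- vapply(seq_len(n_sims), function(i) {
      simulate_activation_test(design, box, hrf, noise,
                               with_noise = cells$with_noise[ci],
                               n_reject = cells$n_rejected[ci],
                               alpha = alpha, config = config,
                               sim_seed = derive_seed(seed, i))
    }, logical(1L))
    cells$power[ci] <- mean(hits)
  }
  cells
}

#' False-negative rate with and without adaptive rejection
#'
#' Generates a batch of noisy synthetic recordings (spikes and baseline
#' shifts injected), optimizes the criterion thresholds over a grid for the
#' lowest false-negative rate under the acceptance-rate-controlled engine,
#' and reports the resulting rate next to the no-rejection rate on the same
#' signals. The false-negative rate is the fraction of signals whose
#' activation (a true positive by construction) fails the one-tailed t-test.
#'
#' @param n_signals Number of synthetic recordings.
#' @param snr_db Either a single SNR or a vector sampled per signal (e.g. a
#'   negatively skewed distribution standing in for real-data quality).
#' @param box A [boxcar_params()]; ratio 1 by default.
#' @param c1_grid,c2_grid,c3_grid Threshold grids searched (criteria 1 to 3).
#' @param acceptance_rate Engine floor. Default 3.
#' @param design,hrf,alpha,config,seed As in [power_simulation()].
#' @return List with `beta_with`, `beta_without`, `best` (optimal
#'   thresholds), and the full `grid` results.
#' @export
fnr_experiment <- function(n_signals = 200L,
                           snr_db = 0,
                           box = boxcar_params(mean_amp = 0.2, ratio = 1),
                           c1_grid = c(0.01, 0.03, 0.05),
                           c2_grid = c(0.01, 0.029),
                           c3_grid = 0.6,
                           acceptance_rate = 3L,
                           design = block_design(),
                           hrf = hrf_params(),
                           alpha = 0.05,
                           config = preprocess_config(),
                           seed = 1L) {
  snrs <- if (length(snr_db) == 1L) rep(snr_db, n_signals) else {
    set.seed(derive_seed(seed, 0L))
    sample(snr_db, n_signals, replace = TRUE)
  }
  sets <- vector("list", n_signals)
  for (i in seq_len(n_signals)) {
    set.seed(derive_seed(seed, i))
    noise <- noise_model_params(snr_db = snrs[i])
    syn <- generate_recording(design, box, hrf, noise, with_noise = TRUE)
    rec <- preprocess(syn$recording, config)
    sets[[i]] <- extract_epochs(rec, design)
  }
  beta_of <- function(policy) {
    miss <- vapply(sets, function(es) {
      if (!is.null(policy)) {
        es <- set_retained(es, quiet_rejection(es, policy))
      }
      act <- epoch_activation(normalize_baseline(es))$activation
      !isTRUE(activation_ttest(act, alpha = alpha)$significant)
    }, logical(1L))
    mean(miss)
  }
  beta_without <- beta_of(NULL)
  grid <- expand.grid(c1 = c1_grid, c2 = c2_grid, c3 = c3_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$beta <- vapply(seq_len(nrow(grid)), function(g) {
    policy <- rejection_policy(
      criteria = list(criterion1_config(jump_threshold = grid$c1[g]),
                      criterion2_config(slope_threshold = grid$c2[g]),
                      criterion3_config(k_iqr = grid$c3[g])),
      acceptance_rate = acceptance_rate)
    beta_of(policy)
  }, numeric(1L))
  best <- grid[which.min(grid$beta), , drop = FALSE]
  list(beta_with = best$beta, beta_without = beta_without,
       best = best[, c("c1", "c2", "c3")], grid = grid)
}

#' Recovery of the true hemodynamic response after rejection
#'
#' Root-mean-square error between the epoch-averaged waveform and the true
#' task response, with the current rejection applied versus averaging all
#' epochs. Both averages and the truth are baseline-normalized before
#' comparison, matching the analysis pipeline. Only meaningful for
#' synthetic data, where the truth is known.
#'
#' @param es A (preprocessed) `epoch_set` whose `retained` vector reflects
#'   the rejection under evaluation.
#' @param truth Numeric vector: the clean task-related epoch waveform on
#'   the same time axis as `es`.
#' @return List with `rmse_rejected` and `rmse_all`.
#' @export
hrf_recovery_score <- function(es, truth) {
  stopifnot(inherits(es, "epoch_set"), length(truth) == ncol(es$data))
  d <- es$design
  base_idx <- epoch_window_idx(es$times, -d$pre_s, -d$pre_s + d$baseline_s)
  norm <- function(x) x - mean(x[base_idx])
  truth_n <- norm(truth)
  avg_of <- function(keep) norm(colMeans(es$data[keep, , drop = FALSE]))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  list(rmse_rejected = rmse(avg_of(which(es$retained)), truth_n),
       rmse_all = rmse(avg_of(seq_len(nrow(es$data))), truth_n))
}
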