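# Shared builders for the test suite. Everything is generated in code; no
# fixtures are read from disk unless a test writes them first.

# A compact design whose epoch windows tile a short recording exactly:
# trial spacing (stim + rest) equals the window length (pre + stim + post).
tiling_design <- function(n_trials = 3L) {
  block_design(n_trials = n_trials, pre_s = 2, baseline_s = 1.5,
               stim_s = 4, post_s = 2, rest_s = 4)
}

# Random epoch matrix with the geometry of the default design.
random_epochs <- function(n_epochs = 6L, design = block_design(), dt = 0.1,
                          sd = 0.1) {
  len <- as.integer(round((design$pre_s + design$stim_s + design$post_s) / dt))
  matrix(rnorm(n_epochs * len, sd = sd), nrow = n_epochs)
}

random_epoch_set <- function(n_epochs = 6L, design = block_design(), sd = 0.1) {
  as_epoch_set(random_epochs(n_epochs, design, sd = sd), design)
}

# True task-response epoch waveform of a synthetic recording, run through
# the same preprocessing as the data it is compared with.
truth_epoch <- function(syn, config = preprocess_config()) {
  rec <- continuous_recording(syn$task,
                              trial_onsets = syn$recording$trial_onsets)
  es <- extract_epochs(preprocess(rec, config), syn$design)
  colMeans(es$data)
}

# Stage descriptors with fixed flag patterns (bit masks over epochs),
# bypassing the detectors: used to exercise the engine in isolation.
mask_stages <- function(masks, severities = NULL, n_epochs = 6L) {
  lapply(seq_along(masks), function(s) {
    eps <- which(bitwAnd(masks[[s]], bitwShiftL(1L, 0:(n_epochs - 1L))) != 0L)
    sev <- if (is.null(severities)) rep(1, length(eps)) else severities[[s]]
    list(id = s, detect = local({
      eps_s <- eps; sev_s <- sev
      function(retained) {
        keep <- eps_s %in% retained
        data.frame(epoch = eps_s[keep], severity = sev_s[keep])
      }
    }))
  })
}

# Literal transcription of the five-step rejection process plus the noise-
# level ranking, written independently of the engine: plain loops, explicit
# counting, its own mid-rank formula. `severity_sets[[s]]` holds one
# severity per epoch in `flag_sets[[s]]` (defaults to all-equal).
oracle_rejection <- function(flag_sets, n_epochs, acceptance,
                             severity_sets = NULL) {
  if (is.null(severity_sets)) {
    severity_sets <- lapply(flag_sets, function(f) rep(1, length(f)))
  }
  unlimited <- identical(acceptance, "unlimited")
  floor_n <- if (unlimited) 0L else acceptance
  retained <- seq_len(n_epochs)
  rec_flags <- vector("list", length(flag_sets))
  rec_sev <- vector("list", length(flag_sets))
  for (s in seq_along(flag_sets)) {
    # (1) identify noisy epochs among the remaining ones
    in_ret <- flag_sets[[s]] %in% retained
    flagged <- flag_sets[[s]][in_ret]
    # (2) count how many would remain after rejection
    remaining_after <- length(retained) - length(flagged)
    # (3, 4) reject only if the acceptance rate is still met
    if (remaining_after >= floor_n) {
      retained <- setdiff(retained, flagged)
      rec_flags[[s]] <- integer(0L); rec_sev[[s]] <- numeric(0L)
    } else {
      rec_flags[[s]] <- flagged; rec_sev[[s]] <- severity_sets[[s]][in_ret]
    }
    # (5) next criterion applies to the remaining epochs only
  }
  if (!unlimited) {
    # noise level and severity-rank sum per epoch, mid-ranks for ties
    level <- integer(n_epochs)
    ranksum <- numeric(n_epochs)
    for (s in seq_along(rec_flags)) {
      fl <- rec_flags[[s]]; sv <- rec_sev[[s]]
      for (k in seq_along(fl)) {
        e <- fl[k]
        level[e] <- level[e] + 1L
        ranksum[e] <- ranksum[e] +
          sum(sv < sv[k]) + (sum(sv == sv[k]) + 1) / 2
      }
    }
    repeat {
      if (length(retained) <= floor_n) break
      noisy <- retained[level[retained] > 0L]
      if (length(noisy) == 0L) break
      worst <- noisy[1L]
      for (e in noisy[-1L]) {
        if (level[e] > level[worst] ||
            (level[e] == level[worst] && ranksum[e] > ranksum[worst])) {
          worst <- e  # equal level and ranksum: earlier epoch kept as worst
        }
      }
      retained <- setdiff(retained, worst)
    }
  }
  sort(retained)
}

# Independent brute-force re-implementations of the detectors, used as
# oracles: plain loops, own statistics, no shared code with the package.
oracle_jump <- function(x, dt, jump, wb_s = 1, recovery = 0.2) {
  n <- length(x)
  pairs <- integer(0L)
  for (i in 1:(n - 1L)) if (abs(x[i + 1L] - x[i]) > jump) pairs <- c(pairs, i)
  if (length(pairs) == 0L) return(NULL)
  events <- list(); cur <- c(pairs[1L], pairs[1L])
  for (p in pairs[-1L]) {
    if (p - cur[2L] - 1L < 2L) cur[2L] <- p else {
      events[[length(events) + 1L]] <- cur; cur <- c(p, p)
    }
  }
  events[[length(events) + 1L]] <- cur
  wb <- round(wb_s / dt)
  shifts <- vapply(events, function(ev) {
    before <- x[max(1L, ev[1L] - wb + 1L):ev[1L]]
    after <- x[(ev[2L] + 1L):min(n, ev[2L] + wb)]
    abs(mean(after) - mean(before))
  }, numeric(1L))
  if (any(shifts > recovery)) max(shifts[shifts > recovery]) else NULL
}

oracle_corr_flags <- function(data, k) {
  n <- nrow(data)
  pear <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  s <- vapply(seq_len(n), function(e) {
    sum(vapply(setdiff(seq_len(n), e), function(o) pear(data[e, ], data[o, ]),
               numeric(1L)))
  }, numeric(1L))
  quart <- function(v, p) {       # linear interpolation at position p*(n-1)
    v <- sort(v); h <- p * (length(v) - 1L)
    lo <- floor(h); v[lo + 1L] + (h - lo) * (v[lo + 2L] - v[lo + 1L])
  }
  q1 <- quart(s, 0.25); q3 <- quart(s, 0.75)
  fence <- q1 - k * (q3 - q1)
  which(s < fence)
}
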