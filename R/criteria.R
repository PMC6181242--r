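#' Criterion 1: sudden amplitude change with recovery failure
#'
#' Configuration of the jump detector. Consecutive-sample amplitude changes
#' above `jump_threshold` mark an over-threshold event; the signal's base
#' level is measured over `base_window_s` before the event onset and after
#' its end, and the event counts as noise only when the base level fails to
#' recover, i.e. shifts by more than `recovery_threshold`.
#'
#' @param jump_threshold Amplitude change between two sampling points, mM·mm
#'   (optimization range 0.01 to 0.05; 0.047 was optimal on real data).
#' @param base_window_s Base-level window, seconds. Default 1.
#' @param recovery_threshold Base-level shift counting as recovery failure,
#'   mM·mm. Default 0.2.
#' @return An object of class `criterion1_config`.
#' @export
criterion1_config <- function(jump_threshold = 0.047, base_window_s = 1,
                              recovery_threshold = 0.2) {
  if (any(c(jump_threshold, base_window_s, recovery_threshold) <= 0)) {
    stop("all criterion-1 parameters must be positive", call. = FALSE)
  }
  structure(list(jump_threshold = jump_threshold, base_window_s = base_window_s,
                 recovery_threshold = recovery_threshold),
            class = c("criterion1_config", "criterion_config"))
}

#' Criterion 2: excessive prestimulus baseline slope
#'
#' Flags epochs whose least-squares slope over the full prestimulus interval
#' (10-s baseline plus 3-s instruction, 13 s in total for the default
#' design) exceeds `slope_threshold` in absolute value. Targets spurious
#' low-frequency physiological oscillations.
#'
#' @param slope_threshold Slope threshold, mM·mm/s (optimization range 0.01
#'   to 0.05; 0.029 was optimal on real data).
#' @return An object of class `criterion2_config`.
#' @export
criterion2_config <- function(slope_threshold = 0.029) {
  if (slope_threshold <= 0) stop("`slope_threshold` must be positive", call. = FALSE)
  structure(list(slope_threshold = slope_threshold),
            class = c("criterion2_config", "criterion_config"))
}

#' Criterion 3: low inter-epoch correlation sum
#'
#' For each epoch, sums its Pearson correlations with every other retained
#' epoch; epochs whose sum falls below the one-sided boxplot-style fence
#' `Q1 - k_iqr * IQR` are flagged as outliers. Unlike criteria 1 and 2 this
#' threshold adapts to the individual data set.
#'
#' @param k_iqr Fence constant (optimization range 0 to 3; 0.6 was optimal
#'   on real data).
#' @return An object of class `criterion3_config`.
#' @export
criterion3_config <- function(k_iqr = 0.6) {
  if (k_iqr < 0) stop("`k_iqr` must be nonnegative", call. = FALSE)
  structure(list(k_iqr = k_iqr),
            class = c("criterion3_config", "criterion_config"))
}

criterion_id <- function(cfg) {
  switch(class(cfg)[1L],
         criterion1_config = 1L, criterion2_config = 2L,
         criterion3_config = 3L,
         stop("unknown criterion config", call. = FALSE))
}

empty_flags <- function() {
  data.frame(epoch = integer(), criterion = integer(), severity = numeric())
}

#' Detect sudden amplitude changes with recovery failure in one epoch
#'
#' Marks consecutive-sample differences exceeding the jump threshold, merges
#' over-threshold runs separated by fewer than two below-threshold samples
#' into single events, measures the base level over `base_window_s` before
#' each event's onset and after its end, and flags the epoch when any event's
#' base level shifts by more than the recovery threshold. Severity is the
#' largest base-level shift among noise events. Base windows truncated below
#' 0.3 s by the epoch edge fall back to the available samples with a warning.
#'
#' @param x Numeric epoch waveform.
#' @param dt Seconds per sample.
#' @param cfg A [criterion1_config()].
#' @return A one-row data frame (`epoch` is `NA`, filled by the caller) when
#'   flagged, otherwise a zero-row data frame.
#' @export
detect_amplitude_jump <- function(x, dt, cfg = criterion1_config()) {
  stopifnot(inherits(cfg, "criterion1_config"))
  wb <- as.integer(round(cfg$base_window_s / dt))
  n <- length(x)
  if (n <= 2L * wb) stop("epoch too short for the base windows", call. = FALSE)
  over <- abs(diff(x)) > cfg$jump_threshold
  if (!any(over)) return(empty_flags())
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by fewer than 2 below-threshold pairs: a multi-
  # sample artifact is one event, not several
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2L:nrow(runs)) {
      gap <- runs[i, 1L] - merged[nrow(merged), 2L] - 1L
      if (gap < 2L) {
        merged[nrow(merged), 2L] <- runs[i, 2L]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  min_w <- max(1L, as.integer(round(0.3 / dt)))
  shifts <- numeric(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    io <- merged[i, 1L]              # last pre-event sample
    ie <- merged[i, 2L] + 1L         # first post-event sample
    ib <- max(1L, io - wb + 1L):io
    ia <- ie:min(n, ie + wb - 1L)
    if (length(ib) < min_w || length(ia) < min_w) {
      warning("base window truncated by epoch edge; using available samples",
              call. = FALSE)
    }
    shifts[i] <- abs(mean(x[ia]) - mean(x[ib]))
  }
  noisy <- shifts > cfg$recovery_threshold
  if (!any(noisy)) return(empty_flags())
  data.frame(epoch = NA_integer_, criterion = 1L, severity = max(shifts[noisy]))
}

#' Detect excessive baseline drift in one epoch
#'
#' Least-squares slope over the prestimulus interval (times in
#' `[-pre_s, 0)`); the epoch is flagged when the absolute slope exceeds the
#' threshold, with the absolute slope as severity.
#'
#' @param x Numeric epoch waveform.
#' @param times Seconds relative to stimulus onset.
#' @param pre_s Prestimulus duration in seconds.
#' @param cfg A [criterion2_config()].
#' @return A one-row data frame when flagged, otherwise zero-row.
#' @export
detect_baseline_drift <- function(x, times, pre_s, cfg = criterion2_config()) {
  stopifnot(inherits(cfg, "criterion2_config"))
  idx <- epoch_window_idx(times, -pre_s, 0)
  if (length(idx) < 2L) stop("prestimulus interval missing", call. = FALSE)
  t <- times[idx]
  y <- x[idx]
  slope <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  if (abs(slope) <= cfg$slope_threshold) return(empty_flags())
  data.frame(epoch = NA_integer_, criterion = 2L, severity = abs(slope))
}

# Pairwise Pearson correlations with zero-variance epochs assigned
# correlation 0 (a flat-lined segment is maximally non-similar under the
# sum statistic, and must remain flaggable).
correlation_sums <- function(data) {
  sds <- apply(data, 1L, stats::sd)
  cm <- suppressWarnings(stats::cor(t(data)))
  cm[!is.finite(cm)] <- 0
  cm[sds == 0, ] <- 0
  cm[, sds == 0] <- 0
  diag(cm) <- 0
  rowSums(cm)
}

#' Detect epochs with outlier-low inter-epoch correlation sums
#'
#' Computes each retained epoch's summed correlation with the other retained
#' epochs and flags those falling strictly below the one-sided fence
#' `Q1 - k_iqr * IQR`. Quartiles use linear interpolation between order
#' statistics ([stats::quantile()] type 7). Requires at least three retained
#' epochs; with fewer the criterion is skipped (zero-row result with a
#' message).
#'
#' @param es An `epoch_set`.
#' @param retained Integer indices of the currently retained epochs.
#' @param cfg A [criterion3_config()].
#' @return Data frame with one row per flagged epoch (columns `epoch`,
#'   `criterion`, `severity` = fence minus sum).
#' @export
detect_low_correlation <- function(es, retained = which(es$retained),
                                   cfg = criterion3_config()) {
  stopifnot(inherits(es, "epoch_set"), inherits(cfg, "criterion3_config"))
  if (length(retained) < 3L) {
    message("criterion 3 skipped: fewer than 3 retained epochs")
    return(empty_flags())
  }
  s <- correlation_sums(es$data[retained, , drop = FALSE])
  q <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[1L] - cfg$k_iqr * (q[2L] - q[1L])
  flagged <- s < fence
  if (!any(flagged)) return(empty_flags())
  data.frame(epoch = retained[flagged], criterion = 3L,
             severity = fence - s[flagged])
}

#' Noise flags of an epoch set under one criterion
#'
#' Applies one criterion to the given epochs and returns all flags raised.
#' Criteria 1 and 2 are per-epoch (each epoch judged in isolation);
#' criterion 3 depends on the whole retained set.
#'
#' @param es An `epoch_set`.
#' @param cfg A criterion configuration.
#' @param retained Integer indices of the epochs to examine.
#' @return Data frame with columns `epoch`, `criterion`, `severity`.
#' @export
noise_flags <- function(es, cfg, retained = which(es$retained)) {
  stopifnot(inherits(es, "epoch_set"))
  id <- criterion_id(cfg)
  if (id == 3L) return(detect_low_correlation(es, retained, cfg))
  out <- lapply(retained, function(e) {
    fl <- if (id == 1L) {
      detect_amplitude_jump(es$data[e, ], es$dt, cfg)
    } else {
      detect_baseline_drift(es$data[e, ], es$times, es$design$pre_s, cfg)
    }
    if (nrow(fl) > 0L) fl$epoch <- e
    fl
  })
  do.call(rbind, c(list(empty_flags()), out))
}
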