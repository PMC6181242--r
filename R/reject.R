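#' Rejection policy: ordered criteria plus an acceptance rate
#'
#' The acceptance rate is the minimum number of epochs that must survive
#' rejection. With a finite acceptance rate the engine refuses any criterion
#' stage that would push the survivor count below the floor (recording the
#' flags instead), and a final ranking pass trims recorded-but-unrejected
#' noisy epochs down to the floor. `"unlimited"` reproduces conventional
#' rejection: every flagged epoch is rejected unconditionally and the
#' ranking pass never fires.
#'
#' @param criteria Ordered list of criterion configurations
#'   ([criterion1_config()], [criterion2_config()], [criterion3_config()]).
#' @param acceptance_rate Positive integer floor, or `"unlimited"`.
#' @return An object of class `rejection_policy`.
#' @export
rejection_policy <- function(criteria = list(criterion1_config(),
                                             criterion2_config(),
                                             criterion3_config()),
                             acceptance_rate = 3L) {
  if (!is.list(criteria) ||
      !all(vapply(criteria, inherits, logical(1L), "criterion_config"))) {
    stop("`criteria` must be a list of criterion configurations", call. = FALSE)
  }
  if (identical(acceptance_rate, "unlimited")) {
    rate <- "unlimited"
  } else {
    rate <- as.integer(acceptance_rate)
    if (is.na(rate) || rate < 1L) {
      stop("`acceptance_rate` must be a positive integer or \"unlimited\"",
           call. = FALSE)
    }
  }
  structure(list(criteria = criteria, acceptance_rate = rate),
            class = "rejection_policy")
}

#' @export
print.rejection_policy <- function(x, ...) {
  ids <- vapply(x$criteria, criterion_id, integer(1L))
  cat(sprintf("rejection policy: criteria %s; acceptance rate %s\n",
              paste(ids, collapse = " -> "),
              if (identical(x$acceptance_rate, "unlimited")) "unlimited"
              else x$acceptance_rate))
  invisible(x)
}

is_unlimited <- function(policy) identical(policy$acceptance_rate, "unlimited")

policy_floor <- function(policy) {
  if (is_unlimited(policy)) 0L else policy$acceptance_rate
}

#' Run the acceptance-rate-controlled rejection engine
#'
#' The engine core, independent of how flags are produced. `stages` is an
#' ordered list; each element is a list with an integer `id` and a function
#' `detect(retained)` returning a data frame with columns `epoch` and
#' `severity` for the flagged epochs among `retained`. The engine performs,
#' per stage: (1) detect flags among the currently retained epochs;
#' (2, 3) check whether rejecting all newly flagged epochs would leave at
#' least `acceptance_rate` survivors; (4) if so reject them all, otherwise
#' reject none and record the flags; (5) pass the survivors to the next
#' stage. After the last stage, recorded flags rank the surviving epochs by
#' noise level (number of recorded flags) and the ranking rejects the
#' noisiest epochs one by one until the floor is reached or no flagged
#' epoch remains. Ties are broken by the larger sum of within-criterion
#' severity ranks, then by the lower epoch index. Severities are not
#' recomputed during the trim (single-pass ranking).
#'
#' @param stages List of stage descriptors (see above); `detect` may return
#'   a data frame or a plain list with `epoch` and `severity` vectors.
#' @param n_epochs Number of epochs.
#' @param policy A [rejection_policy()] (its `criteria` are ignored here;
#'   only the acceptance rate is used).
#' @param details Assemble the full report (default). With `FALSE` only the
#'   retained indices are returned (same decisions, no bookkeeping), which
#'   matters when the engine is run hundreds of thousands of times.
#' @return A list of class `rejection_result`: integer `retained`, data
#'   frame `rejected` (`epoch`, `stage`, `cause`), and `ledger` (one row per
#'   flag ever raised: `epoch`, `criterion`, `stage`, `severity`, `action`).
#'   With `details = FALSE`, a plain list with element `retained`.
#' @export
run_rejection <- function(stages, n_epochs, policy, details = TRUE) {
  floor_n <- policy_floor(policy)
  if (floor_n > n_epochs) {
    stop("acceptance rate exceeds the number of epochs", call. = FALSE)
  }
  retained <- seq_len(n_epochs)
  led_epoch <- integer(0L); led_crit <- integer(0L); led_stage <- integer(0L)
  led_sev <- numeric(0L); led_act <- character(0L)
  rej_epoch <- integer(0L); rej_stage <- integer(0L); rej_cause <- character(0L)
  # recorded flags: per criterion, epochs + severities kept for ranking
  rec_epochs <- vector("list", length(stages))
  rec_sevs <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    fl <- stages[[s]]$detect(retained)
    eps <- fl$epoch
    nf <- length(eps)
    if (nf == 0L) { rec_epochs[[s]] <- integer(0L); rec_sevs[[s]] <- numeric(0L); next }
    reject_ok <- (length(retained) - nf) >= floor_n
    if (details) {
      act <- if (reject_ok) "rejected" else "recorded"
      led_epoch <- c(led_epoch, eps)
      led_crit <- c(led_crit, rep(stages[[s]]$id, nf))
      led_stage <- c(led_stage, rep(s, nf))
      led_sev <- c(led_sev, fl$severity)
      led_act <- c(led_act, rep(act, nf))
    }
    if (reject_ok) {
      retained <- setdiff(retained, eps)
      if (details) {
        rej_epoch <- c(rej_epoch, eps)
        rej_stage <- c(rej_stage, rep(s, nf))
        rej_cause <- c(rej_cause, rep(paste0("criterion", stages[[s]]$id), nf))
      }
      rec_epochs[[s]] <- integer(0L); rec_sevs[[s]] <- numeric(0L)
    } else {
      rec_epochs[[s]] <- eps; rec_sevs[[s]] <- fl$severity
    }
  }
  if (!is_unlimited(policy)) {
    # noise level = number of recorded (unrejected) flags per epoch;
    # severity ranks computed once, within criterion
    level <- integer(n_epochs)
    ranksum <- numeric(n_epochs)
    for (s in seq_along(stages)) {
      eps <- rec_epochs[[s]]
      if (length(eps) == 0L) next
      level[eps] <- level[eps] + 1L
      ranksum[eps] <- ranksum[eps] + rank(rec_sevs[[s]], ties.method = "average")
    }
    while (length(retained) > floor_n) {
      cand <- retained[level[retained] > 0L]
      if (length(cand) == 0L) break
      best <- cand[order(-level[cand], -ranksum[cand], cand)][1L]
      retained <- setdiff(retained, best)
      if (details) {
        rej_epoch <- c(rej_epoch, best)
        rej_stage <- c(rej_stage, NA_integer_)
        rej_cause <- c(rej_cause, "ranking")
      }
    }
  }
  # floor invariant: with a finite acceptance rate the engine must never
  # leave fewer survivors than the floor
  if (!is_unlimited(policy) && length(retained) < floor_n) {
    stop("internal error: acceptance-rate floor violated", call. = FALSE)
  }
  if (!details) return(list(retained = sort(retained)))
  structure(list(
    retained = sort(retained),
    rejected = data.frame(epoch = rej_epoch, stage = rej_stage,
                          cause = rej_cause, stringsAsFactors = FALSE),
    ledger = data.frame(epoch = led_epoch, criterion = led_crit,
                        stage = led_stage, severity = led_sev,
                        action = led_act, stringsAsFactors = FALSE),
    n_epochs = n_epochs,
    acceptance_rate = policy$acceptance_rate
  ), class = "rejection_result")
}

#' @export
print.rejection_result <- function(x, ...) {
  cat(sprintf("rejection result: %d of %d epochs retained (%s)\n",
              length(x$retained), x$n_epochs,
              if (nrow(x$rejected) > 0L) {
                paste0("rejected ", paste(x$rejected$epoch, collapse = ", "))
              } else "nothing rejected"))
  invisible(x)
}

# Build stage descriptors from an epoch set and a policy's criteria.
# Criteria 1 and 2 are per-epoch, so their flags are precomputed once and
# subset per stage; criterion 3 is recomputed on the retained subset so its
# fence adapts to the survivors.
make_stage_detectors <- function(es, criteria) {
  lapply(criteria, function(cfg) {
    id <- criterion_id(cfg)
    if (id == 3L) {
      list(id = id, detect = function(retained) {
        detect_low_correlation(es, retained, cfg)
      })
    } else {
      all_flags <- noise_flags(es, cfg, retained = seq_len(nrow(es$data)))
      list(id = id, detect = function(retained) {
        all_flags[all_flags$epoch %in% retained, , drop = FALSE]
      })
    }
  })
}

#' Apply the adaptive rejection algorithm to an epoch set
#'
#' Runs the policy's criteria in order through the acceptance-rate-
#' controlled engine (see [run_rejection()]) on the epochs of one channel.
#'
#' @param es An `epoch_set`.
#' @param policy A [rejection_policy()].
#' @return A `rejection_result`; use [set_retained()] to apply it to the
#'   epoch set, or [propagate_rejection()] for other signal types.
#' @export
apply_rejection <- function(es, policy = rejection_policy()) {
  stopifnot(inherits(es, "epoch_set"), inherits(policy, "rejection_policy"))
  stages <- make_stage_detectors(es, policy$criteria)
  run_rejection(stages, nrow(es$data), policy)
}

# apply_rejection without per-epoch diagnostics, for simulation harnesses
# that run it hundreds of times (criterion-1 edge warnings and criterion-3
# skip messages would flood the log).
quiet_rejection <- function(es, policy) {
  suppressMessages(suppressWarnings(apply_rejection(es, policy)))
}

#' Mark an epoch set with a rejection result
#'
#' @param es An `epoch_set`.
#' @param result A `rejection_result` for the same trial structure.
#' @return The epoch set with its `retained` vector updated.
#' @export
set_retained <- function(es, result) {
  stopifnot(inherits(es, "epoch_set"), inherits(result, "rejection_result"))
  if (result$n_epochs != nrow(es$data)) {
    stop("trial count mismatch between result and epoch set", call. = FALSE)
  }
  es$retained <- seq_len(nrow(es$data)) %in% result$retained
  es
}

#' Propagate a rejection decision to other signal types
#'
#' Rejection computed on one signal type (typically oxygenated hemoglobin,
#' whose task response is the most pronounced) is applied unchanged to the
#' epoch sets of the other signal types of the same session. Idempotent.
#'
#' @param result A `rejection_result`.
#' @param epoch_sets List of `epoch_set` objects with the same trial count.
#' @return The list with every `retained` vector set from `result`.
#' @export
propagate_rejection <- function(result, epoch_sets) {
  stopifnot(inherits(result, "rejection_result"))
  lapply(epoch_sets, set_retained, result = result)
}
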