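signal_types <- c("O2Hb", "HHb", "HbTotal")

#' Write a recording to delimited text
#'
#' One CSV with a `time_s` column and one `<channel>_<signaltype>` column
#' per channel (UTF-8, '.' decimal, header row). The reader accepts exactly
#' this dialect.
#'
#' @param rec An [continuous_recording()] or a list of recordings sharing
#'   one grid (e.g. the three signal types of a session).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  recs <- if (inherits(rec, "fnirs_recording")) list(rec) else rec
  stopifnot(all(vapply(recs, inherits, logical(1L), "fnirs_recording")))
  grid <- recs[[1L]]$grid
  df <- data.frame(time_s = (seq_len(grid$n_samples) - 1L) * grid$dt)
  for (r in recs) {
    if (r$grid$n_samples != grid$n_samples || r$grid$dt != grid$dt) {
      stop("all recordings must share one sampling grid", call. = FALSE)
    }
    for (ch in r$channels) {
      df[[paste0(ch, "_", r$signal_type)]] <- r$values[ch, ]
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Expects the dialect of [write_recording()]: first column `time_s` with a
#' uniform step (within 1e-6 s), remaining columns named
#' `<channel>_<signaltype>`. Trial onsets are not stored in the recording
#' file; read them with [read_events()].
#'
#' @param path CSV file path.
#' @param signal_type Signal type to extract; may be omitted when the file
#'   holds a single type.
#' @param trial_onsets Optional onset times (seconds) to attach.
#' @return An [continuous_recording()].
#' @export
read_recording <- function(path, signal_type = NULL, trial_onsets = numeric()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "time_s") {
    stop("recording file must start with a `time_s` column", call. = FALSE)
  }
  if (anyNA(df)) stop("recording file has missing values (ragged rows?)", call. = FALSE)
  steps <- diff(df$time_s)
  if (length(steps) == 0L) stop("recording must have at least 2 samples", call. = FALSE)
  if (max(steps) - min(steps) > 1e-6) {
    bad <- which.max(abs(steps - steps[1L])) + 1L
    stop(sprintf("non-uniform time step near line %d", bad + 1L), call. = FALSE)
  }
  cols <- names(df)[-1L]
  m <- regmatches(cols, regexec("^(.+)_(O2Hb|HHb|HbTotal)$", cols))
  bad <- cols[vapply(m, length, integer(1L)) != 3L]
  if (length(bad) > 0L) {
    stop(sprintf("unrecognized column header(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  chan <- vapply(m, `[`, character(1L), 2L)
  type <- vapply(m, `[`, character(1L), 3L)
  present <- unique(type)
  if (is.null(signal_type)) {
    if (length(present) > 1L) {
      stop(sprintf("file holds several signal types (%s); specify `signal_type`",
                   paste(present, collapse = ", ")), call. = FALSE)
    }
    signal_type <- present
  }
  if (!signal_type %in% present) {
    stop(sprintf("signal type '%s' not in file", signal_type), call. = FALSE)
  }
  keep <- type == signal_type
  values <- t(as.matrix(df[, -1L, drop = FALSE][, keep, drop = FALSE]))
  continuous_recording(values, dt = mean(steps), channels = chan[keep],
                       signal_type = signal_type, trial_onsets = trial_onsets)
}

#' Write / read a trial-onset events table
#'
#' CSV with columns `trial` and `onset_s`.
#'
#' @param onsets Numeric onset times in seconds.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, the numeric
#'   onset vector ordered by trial.
#' @export
write_events <- function(onsets, path) {
  utils::write.csv(data.frame(trial = seq_along(onsets), onset_s = onsets),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("trial", "onset_s") %in% names(df))) {
    stop("events file needs columns `trial` and `onset_s`", call. = FALSE)
  }
  df$onset_s[order(df$trial)]
}

#' Write a rejection report
#'
#' CSV with one row per epoch and channel: `channel, epoch, retained,
#' cause, stage, severity`. Retained epochs carry empty cause/stage/
#' severity. `results` may be a single `rejection_result` or a named list
#' keyed by channel.
#'
#' @param results A `rejection_result` or named list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "rejection_result")) results <- list(CH1 = results)
  rows <- lapply(names(results), function(ch) {
    res <- results[[ch]]
    df <- data.frame(channel = ch, epoch = seq_len(res$n_epochs),
                     retained = seq_len(res$n_epochs) %in% res$retained,
                     cause = NA_character_, stage = NA_integer_,
                     severity = NA_real_, stringsAsFactors = FALSE)
    if (nrow(res$rejected) > 0L) {
      i <- match(res$rejected$epoch, df$epoch)
      df$cause[i] <- res$rejected$cause
      df$stage[i] <- res$rejected$stage
      sev <- res$ledger
      for (k in seq_len(nrow(res$rejected))) {
        e <- res$rejected$epoch[k]
        s <- sev$severity[sev$epoch == e]
        if (length(s) > 0L) df$severity[i[k]] <- max(s)
      }
    }
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read reference rejection labels
#'
#' CSV with columns `subject, channel, epoch, rejected` (e.g. from visual
#' inspection), used as the reference of [rejection_accuracy()].
#'
#' @param path File path.
#' @return Data frame with those four columns; `rejected` is logical.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "channel", "epoch", "rejected")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("labels file lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  extra <- setdiff(names(df), need)
  if (length(extra) > 0L) {
    stop(sprintf("unknown column(s) in labels file: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  df$rejected <- as.logical(df$rejected)
  df
}

#' Write / read ground-truth annotations
#'
#' JSON serialization of a synthetic recording's injected-event annotation.
#'
#' @param ground_truth The `ground_truth` element of a
#'   [generate_recording()] result.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, the
#'   ground-truth list.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(gt$events) == 0L) {
    gt$events <- data.frame(trial = integer(), type = character(),
                            time_s = numeric(), magnitude = numeric())
  }
  gt
}

#' Write a small synthetic dataset to disk
#'
#' Profiles: `clean` (no artifacts), `spiky` (spike events only), `drifty`
#' (baseline shifts only), `mixed` (the full event mix), and `cohort` (a
#' two-group study, one recording per subject, group A with positive
#' activation and group B null). Each profile writes `recording*.csv`,
#' `events*.csv`, `ground_truth*.json` and a `manifest.json` capturing the
#' profile, seed and package version; identical seeds give identical trees.
#'
#' @param profile One of `"clean"`, `"spiky"`, `"drifty"`, `"mixed"`,
#'   `"cohort"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_subjects Subjects per group for the `cohort` profile. Default 4.
#' @return Character vector of written paths, invisibly.
#' @export
make_fixture <- function(profile = c("clean", "spiky", "drifty", "mixed",
                                     "cohort"),
                         dir, seed = 1L, n_subjects = 4L) {
  profile <- match.arg(profile)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  design <- block_design()
  gen_one <- function(seed_i, with_noise, types = NULL, mean_amp = 0.2) {
    set.seed(seed_i)
    syn <- generate_recording(design, boxcar_params(mean_amp = mean_amp,
                                                    sd_amp = 0.05),
                              noise = noise_model_params(snr_db = 5,
                                                         machine_ref_amp = 0.2),
                              with_noise = with_noise)
    if (!is.null(types) && nrow(syn$ground_truth$events) > 0L &&
        !all(syn$ground_truth$events$type %in% types)) {
      return(NULL)
    }
    syn
  }
  gen_typed <- function(seed_i, types) {
    # redraw until the random event mix matches the profile's event types
    for (k in 0:200) {
      syn <- gen_one(seed_i + 100003L * k, with_noise = TRUE, types = types)
      if (!is.null(syn)) return(syn)
    }
    stop("could not realize the requested event mix", call. = FALSE)
  }
  emit <- function(syn, stem) {
    p1 <- file.path(dir, paste0(stem, ".csv"))
    p2 <- file.path(dir, paste0(stem, "_events.csv"))
    p3 <- file.path(dir, paste0(stem, "_ground_truth.json"))
    write_recording(syn$recording, p1)
    write_events(syn$recording$trial_onsets, p2)
    write_ground_truth(syn$ground_truth, p3)
    c(p1, p2, p3)
  }
  if (profile == "cohort") {
    for (g in c("A", "B")) {
      for (s in seq_len(n_subjects)) {
        syn <- gen_one(derive_seed(seed, (if (g == "A") 0L else 500L) + s),
                       with_noise = FALSE,
                       mean_amp = if (g == "A") 0.25 else 0)
        paths <- c(paths, emit(syn, sprintf("group%s_subj%02d", g, s)))
      }
    }
  } else {
    syn <- switch(profile,
                  clean = gen_one(derive_seed(seed, 1L), with_noise = FALSE),
                  spiky = gen_typed(derive_seed(seed, 2L),
                                    c("spike", "nonrecovery_spike")),
                  drifty = gen_typed(derive_seed(seed, 3L), "baseline_shift"),
                  mixed = gen_one(derive_seed(seed, 4L), with_noise = TRUE))
    paths <- c(paths, emit(syn, profile))
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(profile = profile, seed = seed,
                            n_subjects = if (profile == "cohort") n_subjects else NULL,
                            package = "nirsreject",
                            version = as.character(utils::packageVersion("nirsreject"))),
                       manifest, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, manifest)
  invisible(paths)
}
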