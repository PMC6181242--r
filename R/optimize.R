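#' A reproducibility target for a subject group
#'
#' Optimization against previously established group-level inferences works
#' by re-running the activation analysis after rejection and checking
#' whether each expected statistical outcome is reproduced. A target names a
#' contrast over the cohort's groups, the expected outcome of the one-tailed
#' one-sample t-test (`alpha = 0.025` by convention), and is satisfied when
#' observed significance matches the expectation.
#'
#' Contrasts: `"group"` is the plain per-subject activation of `group`;
#' `"preadministration"` is the per-subject mean of the `premedication` and
#' `preplacebo` groups; `"intermedication"` is the per-subject
#' difference-of-differences `(postmedication - premedication) -
#' (postplacebo - preplacebo)`.
#'
#' @param name Label of the target.
#' @param expected `"significant"` or `"not_significant"`.
#' @param contrast One of `"group"`, `"preadministration"`,
#'   `"intermedication"`.
#' @param group Group name (required for the `"group"` contrast).
#' @param alpha Significance level. Default 0.025.
#' @return An object of class `stat_target`.
#' @export
stat_target <- function(name, expected = c("significant", "not_significant"),
                        contrast = c("group", "preadministration",
                                     "intermedication"),
                        group = NULL, alpha = 0.025) {
  expected <- match.arg(expected)
  contrast <- match.arg(contrast)
  if (contrast == "group" && is.null(group)) {
    stop("the \"group\" contrast requires `group`", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)", call. = FALSE)
  structure(list(name = name, expected = expected, contrast = contrast,
                 group = group, alpha = alpha), class = "stat_target")
}

contrast_values <- function(target, act) {
  need <- function(g) {
    if (!g %in% colnames(act)) {
      stop(sprintf("group '%s' absent from the cohort", g), call. = FALSE)
    }
    act[, g]
  }
  switch(target$contrast,
         group = need(target$group),
         preadministration = (need("premedication") + need("preplacebo")) / 2,
         intermedication = (need("postmedication") - need("premedication")) -
           (need("postplacebo") - need("preplacebo")))
}

#' Assemble a cohort of epoch sets grouped by condition
#'
#' @param groups Named list; each element is a list of `epoch_set` objects,
#'   one per subject, subject-aligned across groups.
#' @param task Optional task label.
#' @return An object of class `fnirs_cohort`.
#' @export
fnirs_cohort <- function(groups, task = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  ns <- unique(vapply(groups, length, integer(1L)))
  if (length(ns) != 1L) {
    stop("all groups must contain the same number of subjects", call. = FALSE)
  }
  structure(list(groups = groups, n_subjects = ns, task = task),
            class = "fnirs_cohort")
}

#' Simulate a cohort with known group-level activation
#'
#' Generates one synthetic recording per subject and group, preprocesses
#' it and extracts epochs; each subject's response amplitude in a group is
#' drawn from a Gaussian with the group's mean and `between_sd`. Used to
#' exercise the reproducibility machinery on data with a known answer.
#'
#' @param n_subjects Subjects per group.
#' @param group_means Named numeric vector of group activation means.
#' @param between_sd Between-subject amplitude SD. Default 0.05.
#' @param snr_db SNR of every recording. Default 5.
#' @param with_noise Inject artifact events? Default `FALSE`.
#' @param design,hrf,config As elsewhere.
#' @param seed Integer seed.
#' @return An `fnirs_cohort` (epoch sets preprocessed, not yet normalized).
#' @export
simulate_cohort <- function(n_subjects, group_means, between_sd = 0.05,
                            snr_db = 5, with_noise = FALSE,
                            design = block_design(), hrf = hrf_params(),
                            config = preprocess_config(), seed = 1L) {
  stopifnot(!is.null(names(group_means)))
  groups <- lapply(seq_along(group_means), function(g) {
    lapply(seq_len(n_subjects), function(s) {
      set.seed(derive_seed(seed, g * 10000L + s))
      box <- boxcar_params(mean_amp = max(group_means[g], 0),
                           sd_amp = between_sd)
      noise <- noise_model_params(snr_db = snr_db, machine_ref_amp = 0.2)
      syn <- generate_recording(design, box, hrf, noise,
                                with_noise = with_noise)
      extract_epochs(preprocess(syn$recording, config), design)
    })
  })
  names(groups) <- names(group_means)
  fnirs_cohort(groups)
}

# Per-subject, per-group mean activation after rejection under `policy`
# (NULL = no rejection).
cohort_activation <- function(cohort, policy) {
  act <- sapply(cohort$groups, function(subjects) {
    vapply(subjects, function(es) {
      if (!is.null(policy)) es <- set_retained(es, quiet_rejection(es, policy))
      mean(epoch_activation(normalize_baseline(es))$activation)
    }, numeric(1L))
  })
  if (is.null(dim(act))) act <- matrix(act, nrow = 1L,
                                       dimnames = list(NULL, names(cohort$groups)))
  act
}

#' Fraction of statistical targets reproduced after rejection
#'
#' Runs rejection, baseline normalization and activation analysis for every
#' subject and group, evaluates each target's contrast with a one-tailed
#' one-sample t-test, and returns the fraction of targets whose observed
#' significance matches the expectation. An empty target list scores 1
#' (vacuously reproduced).
#'
#' @param cohort An [fnirs_cohort()].
#' @param policy A [rejection_policy()], or `NULL` for no rejection.
#' @param targets List of [stat_target()] objects.
#' @return Fraction in `[0, 1]`.
#' @export
reproducibility_score <- function(cohort, policy, targets) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  if (length(targets) == 0L) return(1)
  act <- cohort_activation(cohort, policy)
  ok <- vapply(targets, function(tg) {
    vals <- contrast_values(tg, act)
    tt <- activation_ttest(vals, alpha = tg$alpha)
    sig <- isTRUE(tt$significant)
    sig == (tg$expected == "significant")
  }, logical(1L))
  mean(ok)
}

#' Agreement between algorithmic and reference rejections
#'
#' `(TP + TN) / total`, counting a rejected epoch as positive: the fraction
#' of epochs on which the algorithm and the reference labels (e.g. visual
#' inspection) agree. Invariant under simultaneous relabeling of both
#' arguments.
#'
#' @param predicted Logical vector: epoch rejected by the algorithm.
#' @param reference Logical vector of the same length: reference labels.
#' @return Fraction in `[0, 1]`.
#' @export
rejection_accuracy <- function(predicted, reference) {
  predicted <- as.logical(predicted)
  reference <- as.logical(reference)
  if (length(predicted) != length(reference)) {
    stop("predicted and reference labels are misaligned", call. = FALSE)
  }
  mean(predicted == reference)
}

#' Grid of candidate rejection policies
#'
#' Spans acceptance rates, criteria subsets (in the fixed order 1 -> 2 -> 3)
#' and per-criterion threshold grids. The full threshold grids used for
#' real-data optimization are 0.01 to 0.05 in steps of 0.001 for criteria 1
#' and 2 and 0 to 3 in steps of 0.1 for criterion 3; the defaults here are
#' five-fold coarser so that a full search stays desk-scale, with the fine
#' grids available by argument.
#'
#' @param acceptance_rates List of acceptance rates (integers and/or
#'   `"unlimited"`).
#' @param criteria_subsets List of integer vectors naming the criteria used
#'   (subsets of `1:3`, possibly empty).
#' @param c1_grid,c2_grid Threshold grids for criteria 1 and 2 (mM·mm and
#'   mM·mm/s).
#' @param c3_grid Fence-constant grid for criterion 3.
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(acceptance_rates = list(3L, 4L),
                           criteria_subsets = list(1:3, c(1L, 2L), c(1L, 3L),
                                                   c(2L, 3L), 1L, 2L, 3L,
                                                   integer(0L)),
                           c1_grid = seq(0.01, 0.05, by = 0.005),
                           c2_grid = seq(0.01, 0.05, by = 0.005),
                           c3_grid = seq(0, 3, by = 0.5)) {
  structure(list(acceptance_rates = acceptance_rates,
                 criteria_subsets = criteria_subsets,
                 c1_grid = c1_grid, c2_grid = c2_grid, c3_grid = c3_grid),
            class = "parameter_grid")
}

#' Enumerate the policies of a parameter grid
#'
#' @param grid A [parameter_grid()].
#' @return Data frame with one row per cell: `acceptance`, `criteria`
#'   (string such as `"1+3"`), `c1`, `c2`, `c3` (NA when the criterion is
#'   not in the subset), and a list column `policy` of
#'   [rejection_policy()] objects.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  rows <- list()
  for (acc in grid$acceptance_rates) {
    for (subset in grid$criteria_subsets) {
      thr <- list(
        c1 = if (1L %in% subset) grid$c1_grid else NA_real_,
        c2 = if (2L %in% subset) grid$c2_grid else NA_real_,
        c3 = if (3L %in% subset) grid$c3_grid else NA_real_)
      combos <- expand.grid(c1 = thr$c1, c2 = thr$c2, c3 = thr$c3,
                            KEEP.OUT.ATTRS = FALSE)
      combos$acceptance <- if (identical(acc, "unlimited")) "unlimited" else
        as.character(acc)
      combos$criteria <- if (length(subset) > 0L) {
        paste(sort(subset), collapse = "+")
      } else "none"
      rows[[length(rows) + 1L]] <- combos
    }
  }
  cells <- do.call(rbind, rows)
  cells$policy <- lapply(seq_len(nrow(cells)), function(i) {
    crits <- list()
    if (!is.na(cells$c1[i])) crits <- c(crits, list(criterion1_config(jump_threshold = cells$c1[i])))
    if (!is.na(cells$c2[i])) crits <- c(crits, list(criterion2_config(slope_threshold = cells$c2[i])))
    if (!is.na(cells$c3[i])) crits <- c(crits, list(criterion3_config(k_iqr = cells$c3[i])))
    acc <- cells$acceptance[i]
    rejection_policy(criteria = crits,
                     acceptance_rate = if (acc == "unlimited") "unlimited" else
                       as.integer(acc))
  })
  cells[, c("acceptance", "criteria", "c1", "c2", "c3", "policy")]
}

#' Search rejection policies for reproducibility across datasets
#'
#' Independent mode scores every grid cell on every dataset and ranks by
#' cumulative reproducibility. Sequential mode first scores the training
#' dataset (the first element of `datasets`), keeps only the training-
#' optimal cells, re-scores those on the validation datasets, and ranks the
#' survivors; its surviving policies are by construction a subset of the
#' training-optimal independent-mode policies. When reference labels are
#' given, rejection accuracy against them is the ranking tie-breaker.
#'
#' @param datasets List of [fnirs_cohort()] objects (training first).
#' @param grid A [parameter_grid()].
#' @param targets List of [stat_target()] objects applied to every dataset.
#' @param reference Optional data frame of reference labels with columns
#'   `group`, `subject`, `epoch`, `rejected`, evaluated on the first
#'   dataset.
#' @param mode `"independent"` or `"sequential"`.
#' @return List with `table` (ranked data frame of cells and scores),
#'   `mode` and `n_cells`.
#' @export
grid_search <- function(datasets, grid, targets, reference = NULL,
                        mode = c("independent", "sequential")) {
  mode <- match.arg(mode)
  stopifnot(length(datasets) >= 1L)
  if (mode == "sequential" && length(datasets) < 2L) {
    stop("sequential mode requires a training and at least one validation dataset",
         call. = FALSE)
  }
  cells <- grid_cells(grid)
  if (nrow(cells) == 0L) stop("empty parameter grid", call. = FALSE)
  score_on <- function(idx, dataset) {
    vapply(idx, function(i) {
      reproducibility_score(dataset, cells$policy[[i]], targets)
    }, numeric(1L))
  }
  ds_names <- paste0("score_", seq_along(datasets))
  for (nm in ds_names) cells[[nm]] <- NA_real_
  if (mode == "independent") {
    for (d in seq_along(datasets)) {
      cells[[ds_names[d]]] <- score_on(seq_len(nrow(cells)), datasets[[d]])
    }
    kept <- seq_len(nrow(cells))
  } else {
    cells[[ds_names[1L]]] <- score_on(seq_len(nrow(cells)), datasets[[1L]])
    best <- max(cells[[ds_names[1L]]])
    kept <- which(cells[[ds_names[1L]]] == best)
    for (d in seq_along(datasets)[-1L]) {
      cells[[ds_names[d]]][kept] <- score_on(kept, datasets[[d]])
    }
  }
  cells$cumulative <- rowSums(as.matrix(cells[, ds_names, drop = FALSE]))
  cells$accuracy <- NA_real_
  if (!is.null(reference)) {
    cells$accuracy[kept] <- vapply(kept, function(i) {
      grid_cell_accuracy(datasets[[1L]], cells$policy[[i]], reference)
    }, numeric(1L))
  }
  ord <- order(-cells$cumulative,
               if (is.null(reference)) seq_len(nrow(cells)) else -cells$accuracy)
  list(table = cells[ord, , drop = FALSE], mode = mode, n_cells = nrow(cells))
}

grid_cell_accuracy <- function(cohort, policy, reference) {
  pred <- c(); ref <- c()
  for (g in names(cohort$groups)) {
    for (s in seq_along(cohort$groups[[g]])) {
      es <- cohort$groups[[g]][[s]]
      res <- quiet_rejection(es, policy)
      n <- nrow(es$data)
      p <- !(seq_len(n) %in% res$retained)
      r <- reference$rejected[reference$group == g & reference$subject == s]
      if (length(r) != n) stop("reference labels misaligned with cohort", call. = FALSE)
      pred <- c(pred, p); ref <- c(ref, r)
    }
  }
  rejection_accuracy(pred, ref)
}
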