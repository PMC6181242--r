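test_that("nothing flagged means nothing rejected", {
  res <- run_rejection(mask_stages(list(0L, 0L, 0L)), 6L, rejection_policy())
  expect_identical(res$retained, 1:6)
  expect_identical(nrow(res$rejected), 0L)
  expect_identical(nrow(res$ledger), 0L)
})

test_that("a stage that would breach the floor records instead of rejecting", {
  # criterion 1 flags four of six epochs; rejecting them would leave two,
  # below the acceptance rate of three, so all four are recorded only
  stages <- mask_stages(list(bitwOr(bitwOr(1L, 2L), bitwOr(4L, 8L)), 0L, 0L))
  res <- run_rejection(stages, 6L, rejection_policy(acceptance_rate = 3L))
  expect_identical(sum(res$ledger$action == "recorded"), 4L)
  expect_identical(sum(res$ledger$action == "rejected"), 0L)
  # ranking then trims the recorded epochs down to the floor
  expect_identical(length(res$retained), 3L)
  expect_true(all(res$rejected$cause == "ranking"))
})

test_that("all-or-none holds within each stage", {
  # stage 1 can reject (6 - 2 >= 3); stage 2 cannot (4 - 2 < 3)
  stages <- mask_stages(list(3L, 12L, 0L))
  res <- run_rejection(stages, 6L, rejection_policy(acceptance_rate = 3L))
  led1 <- res$ledger[res$ledger$stage == 1L, ]
  led2 <- res$ledger[res$ledger$stage == 2L, ]
  expect_true(all(led1$action == "rejected"))
  expect_true(all(led2$action == "recorded"))
})

test_that("ranking rejects by noise level then stops at the floor or flag exhaustion", {
  # both stages breach the floor, so all flags are recorded: epoch 2 twice
  # (stages 1 and 2), epochs 1, 3, 4, 5 once each. The trim removes epoch 2
  # first (highest noise level), then the level-1 tie falls to the lowest
  # index (all severity-rank sums equal), epoch 1, reaching the floor of 4.
  stages <- mask_stages(list(19L, 14L, 0L))  # {1,2,5} then {2,3,4}
  res <- run_rejection(stages, 6L, rejection_policy(acceptance_rate = 4L))
  expect_true(all(res$ledger$action == "recorded"))
  expect_identical(res$rejected$epoch[res$rejected$cause == "ranking"],
                   c(2L, 1L))
  expect_identical(res$retained, 3:6)
  # flag exhaustion before the floor: only epoch 1 flagged, acceptance 3
  res2 <- run_rejection(mask_stages(list(1L, 0L, 1L)), 6L,
                        rejection_policy(acceptance_rate = 3L))
  expect_identical(res2$retained, 2:6)
})

test_that("severity ranks break noise-level ties, then the lower index", {
  # both epochs recorded once; epoch 3 has the higher severity rank
  st <- list(list(id = 1L, detect = function(retained) {
    data.frame(epoch = c(1L, 3L), severity = c(0.1, 0.9))
  }))
  res <- run_rejection(st, 3L, rejection_policy(acceptance_rate = 2L))
  expect_identical(res$rejected$epoch, 3L)
  # equal severities: lower epoch index is trimmed first
  st2 <- list(list(id = 1L, detect = function(retained) {
    data.frame(epoch = c(2L, 4L), severity = c(0.5, 0.5))
  }))
  res2 <- run_rejection(st2, 4L, rejection_policy(acceptance_rate = 3L))
  expect_identical(res2$rejected$epoch, 2L)
})

test_that("unlimited acceptance reproduces unconditional criterion rejection", {
  set.seed(21)
  for (r in 1:50) {
    masks <- as.list(sample(0:63, 3L, replace = TRUE))
    res <- run_rejection(mask_stages(masks), 6L,
                         rejection_policy(acceptance_rate = "unlimited"))
    # equivalent to sequentially removing every flagged epoch
    want <- 1:6
    for (m in masks) {
      want <- setdiff(want, which(bitwAnd(m, bitwShiftL(1L, 0:5)) != 0L))
    }
    expect_identical(res$retained, sort(want))
    expect_true(all(res$ledger$action == "rejected"))
  }
})

test_that("the floor invariant holds over random epoch data end to end", {
  d <- block_design()
  set.seed(31)
  for (r in 1:40) {
    data <- random_epochs(6L, d, sd = 0.2)
    if (r %% 2 == 0) data[sample(6L, 2L), 100:500] <- 0.5   # plant artifacts
    es <- as_epoch_set(data, d)
    for (acc in list(3L, 4L, 6L)) {
      res <- suppressWarnings(suppressMessages(
        apply_rejection(es, rejection_policy(
          criteria = list(criterion1_config(0.05, recovery_threshold = 0.1),
                          criterion2_config(0.02), criterion3_config(0.3)),
          acceptance_rate = acc))))
      expect_gte(length(res$retained), acc)
      expect_identical(sort(c(res$retained, res$rejected$epoch)), 1:6)
      # every rejected epoch appears in the ledger unless trimmed by rank
      for (e in res$rejected$epoch[res$rejected$cause != "ranking"]) {
        expect_true(e %in% res$ledger$epoch)
      }
    }
  }
})

test_that("the engine is deterministic", {
  d <- block_design()
  set.seed(41)
  es <- as_epoch_set(random_epochs(6L, d, sd = 0.2), d)
  pol <- rejection_policy(acceptance_rate = 3L)
  r1 <- suppressWarnings(suppressMessages(apply_rejection(es, pol)))
  r2 <- suppressWarnings(suppressMessages(apply_rejection(es, pol)))
  expect_identical(r1, r2)
})

test_that("acceptance rates beyond the trial count are a configuration error", {
  expect_error(run_rejection(mask_stages(list(0L)), 4L,
                             rejection_policy(acceptance_rate = 5L)),
               "exceeds")
  expect_error(rejection_policy(acceptance_rate = 0L), "positive integer")
})

test_that("rejections propagate to other signal types and are idempotent", {
  d <- block_design()
  set.seed(51)
  o2 <- as_epoch_set(random_epochs(6L, d), d)
  hhb <- as_epoch_set(random_epochs(6L, d), d, signal_type = "HHb")
  hbt <- as_epoch_set(random_epochs(6L, d), d, signal_type = "HbTotal")
  res <- run_rejection(mask_stages(list(bitwOr(1L, 8L), 0L, 0L)), 6L,
                       rejection_policy(acceptance_rate = 3L))
  out <- propagate_rejection(res, list(hhb, hbt))
  expect_identical(which(out[[1L]]$retained), c(2L, 3L, 5L, 6L))
  expect_identical(which(out[[2L]]$retained), c(2L, 3L, 5L, 6L))
  again <- propagate_rejection(res, out)
  expect_identical(again[[1L]]$retained, out[[1L]]$retained)
  # empty rejection leaves sets unchanged
  res0 <- run_rejection(mask_stages(list(0L)), 6L, rejection_policy())
  expect_true(all(propagate_rejection(res0, list(hhb))[[1L]]$retained))
  # trial-count mismatch is an error
  small <- as_epoch_set(random_epochs(4L, d), d)
  expect_error(propagate_rejection(res, list(small)), "mismatch")
})

test_that("criterion 3 re-adapts its fence to the survivors", {
  d <- block_design()
  set.seed(61)
  base <- sin(2 * pi * seq_len(500L) / 100)
  data <- matrix(rep(base, 6), nrow = 6, byrow = TRUE) +
    random_epochs(6L, d, sd = 0.02)
  data[1L, ] <- -base          # strong outlier
  data[2L, 100:200] <- data[2L, 100:200] + 0.5  # criterion-1 artifact
  es <- as_epoch_set(data, d)
  pol <- rejection_policy(
    criteria = list(criterion1_config(0.3, recovery_threshold = 0.2),
                    criterion3_config(0.6)),
    acceptance_rate = 3L)
  res <- suppressWarnings(apply_rejection(es, pol))
  # stage 2's flags must have been computed among the stage-1 survivors
  led3 <- res$ledger[res$ledger$criterion == 3L, ]
  expect_false(2L %in% led3$epoch)
  expect_true(1L %in% res$rejected$epoch)
})
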