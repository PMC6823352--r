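fake_predictions <- function(stages, p_trigger) {
  # build a prediction tibble with the trigger-stage certainty controlled
  probs <- matrix(0, length(stages), 3)
  for (i in seq_along(stages)) {
    s <- stage_int(stages[i])
    probs[i, s] <- p_trigger[i]
    probs[i, -s] <- (1 - p_trigger[i]) / 2
  }
  tibble::tibble(epoch = seq_along(stages) - 1L,
                 p_wake = probs[, 1], p_nrem = probs[, 2], p_rem = probs[, 3],
                 stage = stage_factor(stages))
}

test_that("candidate selection applies the strict certainty rule at the boundary", {
  pred <- fake_predictions(c("N", "N", "N", "W", "R"),
                           c(0.96, 0.95, 0.80, 0.60, 0.50))
  sel <- select_rescoring_candidates(pred, rescoring_policy())
  # 0.96 above, 0.95 not strictly below, 0.80 selected; WAKE/REM never
  expect_equal(sel, 2L)
  # a WAKE epoch with arbitrarily low certainty is still ineligible
  low_wake <- fake_predictions("W", 0.4)
  expect_equal(length(select_rescoring_candidates(low_wake)), 0)
})

test_that("candidate count is monotone in the threshold", {
  set.seed(41)
  pred <- fake_predictions(sample(c("N", "W", "R"), 200, TRUE), runif(200))
  thr <- c(0.2, 0.5, 0.8, 0.95, 1)
  counts <- vapply(thr, function(th) {
    length(select_rescoring_candidates(
      pred, rescoring_policy(certainty_threshold = th)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("policy validation", {
  expect_error(rescoring_policy(certainty_threshold = 0), "in \\(0, 1\\]")
  expect_error(rescoring_policy(certainty_threshold = 1.2), "in \\(0, 1\\]")
})

test_that("rescoring alters candidates only and logs the changes", {
  cfg <- tiny_config("full")
  man <- make_dataset(1, 20, seed = 51, sampling_rate = 32, epoch_length = 1)
  es <- preprocess_record(man$record[[1]], epoch_length = 1)
  full <- sleep_model(cfg, 1)
  pred <- predict(full, es)

  rcfg <- tiny_config("rescoring")
  rmodel <- sleep_model(rcfg, 2)
  rmodel$trained <- TRUE

  # a threshold of 1 makes every NREM-labeled epoch a candidate
  pol_all <- rescoring_policy(certainty_threshold = 1)
  out <- apply_rescoring(pred, rmodel, es, pol_all)
  cand <- select_rescoring_candidates(pred, pol_all)
  log <- rescoring_changelog(out)
  expect_setequal(log$epoch, cand)
  untouched <- setdiff(pred$epoch, cand)
  strip <- function(x) { attr(x, "changelog") <- NULL; as.data.frame(x) }
  expect_identical(strip(out[match(untouched, out$epoch), ]),
                   strip(pred[match(untouched, pred$epoch), ]))
  expect_true(all(pred$stage[match(untouched, pred$epoch)] %in%
                    c("WAKE", "REM") |
                    pred$p_nrem[match(untouched, pred$epoch)] >= 1))

  # an unreachable threshold rescored nothing and changes nothing
  tiny_thr <- rescoring_policy(certainty_threshold = 1e-9)
  out0 <- apply_rescoring(pred, rmodel, es, tiny_thr)
  expect_equal(nrow(rescoring_changelog(out0)), 0)
  attr(out0, "changelog") <- NULL
  expect_identical(as.data.frame(out0), as.data.frame(pred))
})

test_that("rescoring never touches WAKE- or REM-labeled epochs", {
  cfg <- tiny_config("full")
  man <- make_dataset(1, 30, seed = 53, sampling_rate = 32, epoch_length = 1)
  es <- preprocess_record(man$record[[1]], epoch_length = 1)
  full <- sleep_model(cfg, 4)
  pred <- predict(full, es)
  rmodel <- sleep_model(tiny_config("rescoring"), 5)
  out <- apply_rescoring(pred, rmodel, es, rescoring_policy(certainty_threshold = 1))
  keep <- pred$stage %in% c("WAKE", "REM")
  expect_identical(out$stage[keep], pred$stage[keep])
  expect_identical(out$p_wake[keep], pred$p_wake[keep])
})

test_that("the candidate pool is less REM-starved than the data it comes from", {
  # premise of the rescoring design: missed REM concentrates among
  # low-certainty non-REM calls.  Construct predictions embodying that
  # premise (true REM mostly called NREM with spread certainty, true NREM
  # mostly called NREM confidently) and verify the selection rule delivers
  # the promised class-balance alleviation.
  set.seed(57)
  truth <- rep(c(2L, 3L), times = c(190, 10))     # 5% REM overall
  called_nrem <- runif(200) < ifelse(truth == 2L, 0.98, 0.7)
  p_nrem <- ifelse(truth == 2L, runif(200, 0.9, 1), runif(200, 0.4, 0.9))
  stage <- ifelse(called_nrem, 2L, truth)
  pred <- tibble::tibble(epoch = 0:199,
                         p_wake = (1 - p_nrem) / 2, p_nrem = p_nrem,
                         p_rem = (1 - p_nrem) / 2,
                         stage = stage_factor(stage))
  cand <- select_rescoring_candidates(pred, rescoring_policy())
  expect_gt(length(cand), 0)
  rem_frac_candidates <- mean(truth[cand + 1L] == 3L)
  expect_gt(rem_frac_candidates, mean(truth == 3L))
})

test_that("training the rescoring model requires candidates and is reproducible", {
  cfg <- tiny_config("full")
  td <- tiny_dataset(2, 40, seed = 55, config = cfg)
  plan <- training_plan(pretrain_epochs = 3, finetune_epochs = 3,
                        pretrain_batch = 16, finetune_batch = 4)
  full <- train_sleep_model(td$manifest$record, td$manifest$hypnogram, cfg,
                            plan, seed = 6)
  expect_error(
    train_rescoring_model(full, td$dataset, plan,
                          rescoring_policy(certainty_threshold = 1e-12),
                          seed = 1),
    "no rescoring candidates")
  r1 <- train_rescoring_model(full, td$dataset, plan,
                              rescoring_policy(certainty_threshold = 1),
                              seed = 7)
  r2 <- train_rescoring_model(full, td$dataset, plan,
                              rescoring_policy(certainty_threshold = 1),
                              seed = 7)
  expect_identical(r1$params, r2$params)
  expect_equal(r1$config$variant, "rescoring")
  expect_false(has_recurrent_parameters(r1))
})
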