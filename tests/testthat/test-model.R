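test_that("configuration validation catches inconsistent settings", {
  expect_error(sleep_model_config(lstm_units = 7), "even")
  expect_error(sleep_model_config(context = 24), "context")
  expect_error(
    sleep_model_config(sampling_rate = 32, epoch_length = 1,
                       narrow_geom = list(k1 = 8, s1 = 2, p1 = 2, k2 = 3,
                                          p2 = 2),
                       wide_geom = list(k1 = 64, s1 = 4, p1 = 2, k2 = 3,
                                        p2 = 1)),
    "longer than epoch")
  expect_error(
    sleep_model_config(sampling_rate = 32, epoch_length = 1,
                       narrow_geom = list(k1 = 8, s1 = 2, p1 = 16, k2 = 3,
                                          p2 = 2)),
    "collapses")
  expect_error(sleep_model_config(dropout_rate = 1), "dropout_rate")
})

test_that("full-scale head widths follow the published sizes", {
  cfg <- sleep_model_config(scale = 1)
  expect_equal(cfg$lstm_units, 1024)
  expect_equal(cfg$lstm_per_dir, 512)
  expect_equal(cfg$fc_units, 1024)
  expect_equal(cfg$context, 25)
  m <- sleep_model(cfg, seed = 1)
  # two bi-LSTM layers, each with forward and backward weight sets
  expect_setequal(grep("^lstm", names(m$params), value = TRUE),
                  c(t(outer(c("lstm1f", "lstm1b", "lstm2f", "lstm2b"),
                            c("_W", "_U", "_b"), paste0))))
  expect_equal(nrow(m$params$lstm1f_U), 4 * 512)
  expect_equal(nrow(m$params$fc_W), 1024)
  expect_equal(nrow(m$params$out_W), 3)
})

test_that("parameter counts scale monotonically and variants differ structurally", {
  n8 <- n_parameters(sleep_model(sleep_model_config(scale = 1 / 8), 1))
  n1 <- n_parameters(sleep_model(sleep_model_config(scale = 1), 1))
  expect_lt(n8, n1)
  resc <- sleep_model(tiny_config("rescoring"), 1)
  expect_false(has_recurrent_parameters(resc))
  full <- sleep_model(tiny_config("full"), 1)
  expect_true(has_recurrent_parameters(full))
})

test_that("an all-zero model predicts the uniform distribution, label WAKE by tie order", {
  cfg <- tiny_config("full")
  m <- sleep_model(cfg, 1)
  m$params <- lapply(m$params, function(p) p * 0)
  man <- make_dataset(1, 8, seed = 2, sampling_rate = 32, epoch_length = 1)
  es <- preprocess_record(man$record[[1]], epoch_length = 1, mode = cfg$rms_mode)
  pred <- predict(m, es)
  expect_equal(pred$p_wake, rep(1 / 3, nrow(pred)))
  expect_equal(pred$p_nrem, rep(1 / 3, nrow(pred)))
  expect_true(all(pred$stage == "WAKE"))
})

test_that("inference is deterministic and aligned to window centers", {
  cfg <- tiny_config("full", dropout_rate = 0.5)   # dropout must not leak
  m <- sleep_model(cfg, 3)
  man <- make_dataset(1, 12, seed = 4, sampling_rate = 32, epoch_length = 1)
  es <- preprocess_record(man$record[[1]], epoch_length = 1, mode = cfg$rms_mode)
  p1 <- predict(m, es)
  p2 <- predict(m, es)
  expect_identical(p1, p2)
  expect_equal(p1$epoch, 2:9)   # context 5: first/last 2 epochs unscored
  expect_equal(attr(p1, "n_epochs"), 12)
  probs <- as.matrix(p1[, c("p_wake", "p_nrem", "p_rem")])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
})

test_that("per-epoch variants score every epoch with normalized certainties", {
  man <- make_dataset(1, 9, seed = 6, sampling_rate = 32, epoch_length = 1)
  es <- preprocess_record(man$record[[1]], epoch_length = 1)
  for (variant in c("pretrain_head", "rescoring")) {
    m <- sleep_model(tiny_config(variant), 5)
    pred <- predict(m, es)
    expect_equal(nrow(pred), 9)
    probs <- as.matrix(pred[, c("p_wake", "p_nrem", "p_rem")])
    expect_equal(unname(rowSums(probs)), rep(1, 9), tolerance = 1e-9)
    expect_true(all(probs >= 0))
  }
})

test_that("the EEG branches are distinct parameter sets, not shared weights", {
  cfg <- tiny_config("full")
  m <- sleep_model(cfg, 7)
  man <- make_dataset(1, 6, seed = 8, sampling_rate = 32, epoch_length = 1)
  es <- preprocess_record(man$record[[1]], epoch_length = 1)
  base <- model_features_for_test(m, es)
  for (branch in c("nar", "wid", "emg")) {
    m2 <- m
    m2$params[[paste0(branch, "_W1")]] <-
      m2$params[[paste0(branch, "_W1")]] + 0.1
    expect_gt(max(abs(model_features_for_test(m2, es) - base)), 0)
  }
})

test_that("save/load round-trips predictions bit-identically and checks variants", {
  cfg <- tiny_config("full")
  m <- sleep_model(cfg, 11)
  man <- make_dataset(1, 10, seed = 10, sampling_rate = 32, epoch_length = 1)
  es <- preprocess_record(man$record[[1]], epoch_length = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict(back, es), predict(m, es))

  expect_error(load_model(path, expect_variant = "rescoring"),
               "variant mismatch.*full.*rescoring")
  saveRDS(list(format = "other"), path)
  expect_error(load_model(path), "not a sleepscorer model")
})

test_that("epoch-geometry mismatches are rejected at predict time", {
  m <- sleep_model(tiny_config("full"), 1)
  man <- make_dataset(1, 6, seed = 2, sampling_rate = 64, epoch_length = 1)
  es <- preprocess_record(man$record[[1]], epoch_length = 1)
  expect_error(predict(m, es), "epoch length mismatch")
})

test_that("tidy() and glance() summarize a model", {
  m <- sleep_model(tiny_config("rescoring"), 1)
  td <- tidy(m)
  expect_true(all(c("term", "n") %in% names(td)))
  expect_equal(sum(td$n), n_parameters(m))
  gl <- glance(m)
  expect_equal(gl$variant, "rescoring")
  expect_false(gl$trained)
})

test_that("compiled gradients match finite differences on every parameter block", {
  cfg <- tiny_config("full")
  cfgp <- tiny_config("pretrain_head")
  cfgr <- tiny_config("rescoring")
  set.seed(99)
  L <- cfg$samples_per_epoch
  n <- 10
  eeg <- matrix(rnorm(L * n), L, n)
  emg <- matrix(rnorm(L * n), L, n)
  y <- sample(1:3, n, replace = TRUE)
  ccfg <- sleepscorer:::cfg_cpp(cfg, dropout = 0)
  # jitter all parameters away from zero so no pre-activation sits exactly
  # on a ReLU kink (finite differences are one-sided there)
  jitter_params <- function(params) {
    lapply(params, function(p) p + matrix(runif(length(p), 0.05, 0.35) *
                                            sample(c(-1, 1), length(p), TRUE),
                                          nrow(p), ncol(p)))
  }

  check_grads <- function(params, grad_call, eps = 1e-4, tol = 2e-4) {
    res <- grad_call(params)
    worst <- 0
    for (nm in names(params)) {
      k <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
      for (i in k) {
        p2 <- params
        p2[[nm]][i] <- p2[[nm]][i] + eps
        lp <- grad_call(p2)$loss
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
        lm <- grad_call(p2)$loss
        gnum <- (lp - lm) / (2 * eps)
        rel <- abs(gnum - res$grads[[nm]][i]) /
          max(1e-6, abs(gnum) + abs(res$grads[[nm]][i]))
        worst <- max(worst, rel)
      }
    }
    expect_lt(worst, tol)
  }

  check_grads(jitter_params(sleep_model(cfgp, 1)$params), function(p) {
    sleepscorer:::cpp_grad_pretrain(eeg, emg, y, p, ccfg, 0)
  })
  check_grads(jitter_params(sleep_model(cfgr, 2)$params), function(p) {
    sleepscorer:::cpp_grad_rescoring(eeg, emg, y, p, ccfg, 0)
  })
  check_grads(jitter_params(sleep_model(cfg, 3)$params), function(p) {
    sleepscorer:::cpp_grad_full(eeg, emg, y, 5L, p, ccfg, 0)
  })
})
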