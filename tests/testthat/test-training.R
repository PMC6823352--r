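test_that("cross-entropy matches its closed forms", {
  perfect <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  expect_equal(cross_entropy_loss(c("W", "N"), perfect), 0)
  uniform <- matrix(1 / 3, 1, 3)
  expect_equal(cross_entropy_loss("R", uniform), log(3))
  # N = 2, probabilities for the true class 0.5 and 0.25:
  # -(ln 0.5 + ln 0.25) / 2 = 1.039721
  pred <- matrix(c(0.5, 0.3, 0.2, 0.25, 0.5, 0.25), 2, 3, byrow = TRUE)
  expect_equal(cross_entropy_loss(c("W", "W"), pred),
               -(log(0.5) + log(0.25)) / 2)
  expect_equal(round(cross_entropy_loss(c("W", "W"), pred), 6), 1.039721)
})

test_that("cross-entropy validates lengths and is permutation-invariant", {
  pred <- matrix(runif(9), 3, 3)
  pred <- pred / rowSums(pred)
  expect_error(cross_entropy_loss(c("W", "N"), pred), "length mismatch")
  y <- c("W", "N", "R")
  ord <- c(3, 1, 2)
  expect_equal(cross_entropy_loss(y[ord], pred[ord, ]),
               cross_entropy_loss(y, pred))
})

make_label_dataset <- function(labels, L = 32) {
  # sentinel-coded epochs: sample 1 carries the label, sample 2 the epoch's
  # original position, so any label/window shuffling is detectable
  n <- length(labels)
  eeg <- matrix(rnorm(L * n, sd = 0.1), L, n)
  eeg[1, ] <- labels
  eeg[2, ] <- seq_len(n)
  structure(list(eeg = eeg, emg = eeg,
                 labels = as.integer(labels),
                 record_id = rep("r1", n), record_end = n,
                 sampling_rate = 32L, epoch_length = 1,
                 normalized = FALSE, rms_mode = "paper"),
            class = "labeled_dataset")
}

test_that("undersampling equalizes to the minority count without replacement", {
  ds <- make_label_dataset(rep(1:3, times = c(100, 50, 10)))
  u <- undersample(ds, seed = 1)
  expect_equal(as.integer(table(u$labels)), rep(10L, 3))
  # without replacement: position sentinels are unique
  expect_equal(anyDuplicated(u$eeg[2, ]), 0)
})

test_that("balancing is deterministic and keeps already balanced data intact", {
  ds <- make_label_dataset(rep(1:3, times = c(7, 7, 7)))
  u <- undersample(ds, seed = 9)
  expect_equal(sort(u$labels), sort(ds$labels))
  expect_identical(undersample(ds, seed = 9), u)
  big <- make_label_dataset(sample(rep(1:3, times = c(30, 20, 5))))
  expect_identical(undersample(big, seed = 4), undersample(big, seed = 4))
  expect_identical(oversample(big, seed = 4), oversample(big, seed = 4))
})

test_that("oversampling tops minorities up to the majority from their own pools", {
  ds <- make_label_dataset(rep(1:3, times = c(100, 50, 10)))
  o <- oversample(ds, seed = 2)
  expect_equal(as.integer(table(o$labels)), rep(100L, 3))
  # every epoch's sentinel still matches its label: pairing preserved and
  # duplicates drawn from the right pool
  expect_true(all(o$eeg[1, ] == o$labels))
  # majority class epochs unchanged
  expect_equal(sum(o$labels == 1), 100)
})

test_that("balancing requires every stage to be present", {
  ds <- make_label_dataset(rep(1:2, times = c(5, 5)))
  expect_error(undersample(ds), "REM")
  expect_error(oversample(ds), "REM")
})

test_that("balancing preserves window-label pairing under sentinels", {
  set.seed(11)
  ds <- make_label_dataset(sample(rep(1:3, times = c(40, 25, 8))))
  for (balanced in list(undersample(ds, 3), oversample(ds, 3))) {
    expect_true(all(balanced$eeg[1, ] == balanced$labels))
    expect_true(all(balanced$emg[1, ] == balanced$labels))
  }
})

test_that("the training plan enforces the learning-rate ordering", {
  expect_error(training_plan(pretrain_lr = 1e-4, finetune_lr = 1e-3),
               "smaller than")
  desk <- training_plan()
  expect_lt(desk$finetune$lr, desk$pretrain$lr)
  paper <- training_plan("paper")
  expect_equal(paper$pretrain$lr, 1e-4)
  expect_equal(paper$finetune$lr, 1e-6)
  expect_equal(paper$pretrain$batch, 100)
  expect_equal(paper$finetune$batch, 10)
})

test_that("a zero learning rate leaves the weights unchanged", {
  set.seed(101)
  ds <- make_label_dataset(rep(1:3, times = c(12, 10, 8)))
  cfg <- tiny_config("pretrain_head")
  m <- sleep_model(cfg, 1)
  plan <- training_plan(pretrain_epochs = 2, pretrain_lr = 0, finetune_lr = 0)
  trained <- pretrain(m, ds, plan, seed = 1)
  expect_identical(trained$params, m$params)
})

test_that("pretraining reduces the balanced training loss and is reproducible", {
  td <- tiny_dataset(2, 60, seed = 17)
  cfg <- tiny_config("pretrain_head")
  plan <- training_plan(pretrain_epochs = 10, pretrain_batch = 16)
  m1 <- pretrain(sleep_model(cfg, 1), td$dataset, plan, seed = 2)
  expect_lt(tail(m1$history$loss, 1), m1$history$loss[1])
  m2 <- pretrain(sleep_model(cfg, 1), td$dataset, plan, seed = 2)
  expect_identical(m1$params, m2$params)
})

test_that("training aborts with a diagnostic when the loss diverges", {
  set.seed(103)
  ds <- make_label_dataset(rep(1:3, times = c(8, 8, 8)))
  cfg <- tiny_config("pretrain_head")
  m <- sleep_model(cfg, 1)
  m$params$head_bp[] <- Inf   # every logit overflows, softmax turns NaN
  expect_error(pretrain(m, ds, training_plan(pretrain_epochs = 1), seed = 1),
               "diverged")
})

test_that("fine-tuning sequences never span a record boundary", {
  cfg <- tiny_config("full")
  td <- tiny_dataset(3, 28, seed = 23, config = cfg)
  seqs <- sleepscorer:::finetune_sequences(td$dataset, cfg$context)
  # 28 epochs per record, context 5 -> 5 sequences per record
  expect_equal(length(seqs), 15)
  rec_of <- td$dataset$record_id
  for (s in seqs) {
    expect_equal(length(unique(rec_of[s])), 1)
    expect_equal(s, s[1]:(s[1] + cfg$context - 1))
  }
  # a chunking offset shifts every sequence but still respects boundaries
  seqs3 <- sleepscorer:::finetune_sequences(td$dataset, cfg$context, offset = 3L)
  expect_equal(length(seqs3), 15)
  for (s in seqs3) expect_equal(length(unique(rec_of[s])), 1)
  expect_equal(seqs3[[1]][1], 4L)
})

test_that("fine-tuning with zero passes returns the transferred initialization", {
  cfg <- tiny_config("full")
  td <- tiny_dataset(1, 30, seed = 29, config = cfg)
  pre <- pretrain(sleep_model(tiny_config("pretrain_head"), 1), td$dataset,
                  training_plan(pretrain_epochs = 2, pretrain_batch = 16),
                  seed = 1)
  base <- sleep_model(cfg, 5)
  m0 <- finetune(base, pre, td$dataset,
                 training_plan(finetune_epochs = 0), seed = 1)
  # extractor weights transferred, head untouched
  expect_identical(m0$params$nar_W1, pre$params$nar_W1)
  expect_identical(m0$params$out_W, base$params$out_W)
  es <- preprocess_record(td$manifest$record[[1]], epoch_length = 1)
  expect_identical(predict(m0, es), {
    m_manual <- base
    m_manual$params[grep("^(nar|wid|emg)_", names(pre$params), value = TRUE)] <-
      pre$params[grep("^(nar|wid|emg)_", names(pre$params), value = TRUE)]
    predict(m_manual, es)
  })
})

test_that("fine-tuning after pretraining does not hurt held-out accuracy", {
  cfg <- tiny_config("full")
  cfg_pre <- tiny_config("pretrain_head")
  train <- tiny_dataset(2, 60, seed = 31, config = cfg)
  test <- tiny_dataset(1, 40, seed = 33, config = cfg)
  plan <- training_plan(pretrain_epochs = 8, finetune_epochs = 30,
                        pretrain_lr = 2e-3, finetune_lr = 1e-3,
                        pretrain_batch = 16, finetune_batch = 4)
  pre <- pretrain(sleep_model(cfg_pre, 1), train$dataset, plan, seed = 3)
  full <- finetune(sleep_model(cfg, 2), pre, train$dataset, plan, seed = 3)

  es <- preprocess_record(test$manifest$record[[1]], epoch_length = 1)
  truth <- test$manifest$hypnogram[[1]]
  acc <- function(m) {
    pred <- predict(m, es)
    mean(as.character(pred$stage) ==
           as.character(truth$stage[match(pred$epoch, truth$epoch)]))
  }
  expect_gte(acc(full), acc(pre))
  # determinism of the whole two-step run
  full2 <- finetune(sleep_model(cfg, 2),
                    pretrain(sleep_model(cfg_pre, 1), train$dataset, plan,
                             seed = 3),
                    train$dataset, plan, seed = 3)
  expect_identical(full$params, full2$params)
})
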