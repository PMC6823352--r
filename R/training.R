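#' Categorical cross-entropy loss
#'
#' `L = -(1/N) * sum_i y_i . log(yhat_i)` over N epochs, with predictions
#' clipped at 1e-12 before the logarithm.
#'
#' @param true_labels One-hot numeric matrix (N x 3), or stage labels
#'   (factor/character/integer) which are one-hot encoded.
#' @param predicted Numeric matrix (N x 3) of probability rows.
#' @return Non-negative scalar loss.
#' @examples
#' cross_entropy_loss(c("W", "N"), matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE))
#' @export
cross_entropy_loss <- function(true_labels, predicted) {
  predicted <- as.matrix(predicted)
  if (is.matrix(true_labels) && ncol(true_labels) == 3) {
    Y <- true_labels
  } else {
    y <- stage_int(true_labels)
    Y <- matrix(0, length(y), 3)
    Y[cbind(seq_along(y), y)] <- 1
  }
  if (nrow(Y) != nrow(predicted)) {
    abort(sprintf("length mismatch: %d labels vs %d predictions",
                  nrow(Y), nrow(predicted)))
  }
  -mean(rowSums(Y * log(pmax(predicted, 1e-12))))
}

#' Build a labeled training dataset
#'
#' Pairs preprocessed epochs with expert stage labels across one or more
#' records, remembering record boundaries so no training sequence ever spans
#' two records.
#'
#' @param records List of [signal_record()]s (or a single one).
#' @param hypnograms List of matching [hypnogram()]s.
#' @param config A [sleep_model_config()]; supplies epoch length, RMS mode
#'   and normalization choice.
#' @return A `labeled_dataset`: combined epoch matrices, integer labels,
#'   and per-record index ranges.
#' @export
labeled_dataset <- function(records, hypnograms, config) {
  if (inherits(records, "signal_record")) records <- list(records)
  if (inherits(hypnograms, "hypnogram")) hypnograms <- list(hypnograms)
  stopifnot(length(records) == length(hypnograms), length(records) >= 1)
  eeg <- vector("list", length(records))
  emg <- vector("list", length(records))
  labels <- vector("list", length(records))
  ids <- character(length(records))
  for (i in seq_along(records)) {
    es <- preprocess_record(records[[i]], epoch_length = config$epoch_length,
                            mode = config$rms_mode,
                            normalize = config$normalize)
    h <- hypnograms[[i]]
    n <- min(n_epochs(es), nrow(h))
    if (n < 1) abort("record/hypnogram pair yields no labeled epochs")
    eeg[[i]] <- es$eeg[, seq_len(n), drop = FALSE]
    emg[[i]] <- es$emg[, seq_len(n), drop = FALSE]
    labels[[i]] <- as.integer(h$stage[seq_len(n)])
    ids[i] <- es$record_id
  }
  counts <- vapply(labels, length, integer(1))
  structure(list(eeg = do.call(cbind, eeg), emg = do.call(cbind, emg),
                 labels = unlist(labels),
                 record_id = rep(ids, counts),
                 record_end = cumsum(counts),
                 sampling_rate = records[[1]]$sampling_rate,
                 epoch_length = config$epoch_length,
                 normalized = config$normalize, rms_mode = config$rms_mode),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(factor(STAGE_LEVELS[x$labels], levels = STAGE_LEVELS))
  cat(sprintf("<labeled_dataset> %d epochs over %d record(s): %s\n",
              length(x$labels), length(unique(x$record_id)),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

dataset_subset <- function(dataset, idx) {
  out <- dataset
  out$eeg <- dataset$eeg[, idx, drop = FALSE]
  out$emg <- dataset$emg[, idx, drop = FALSE]
  out$labels <- dataset$labels[idx]
  out$record_id <- dataset$record_id[idx]
  out$record_end <- cumsum(rle(out$record_id)$lengths)
  out
}

check_all_stages_present <- function(labels) {
  missing <- setdiff(1:3, unique(labels))
  if (length(missing)) {
    abort(sprintf("stage(s) absent from dataset: %s",
                  paste(STAGE_LEVELS[missing], collapse = ", ")))
  }
}

#' Balance a dataset by undersampling
#'
#' Reduces every stage to the minority stage's epoch count by sampling
#' without replacement (used before pretraining so the feature extractor
#' sees the three stages equally often).
#'
#' @param dataset A [labeled_dataset()].
#' @param seed Integer seed.
#' @return A balanced `labeled_dataset`.
#' @export
undersample <- function(dataset, seed = 1L) {
  check_all_stages_present(dataset$labels)
  set.seed(seed)
  m <- min(table(dataset$labels))
  idx <- sort(unlist(lapply(1:3, function(s) {
    pool <- which(dataset$labels == s)
    sample(pool, m)
  })))
  dataset_subset(dataset, idx)
}

#' Balance a dataset by oversampling
#'
#' Raises every stage to the majority stage's epoch count: all original
#' epochs are kept and minority stages are topped up by sampling with
#' replacement from their own pool.
#'
#' @inheritParams undersample
#' @return A balanced `labeled_dataset`.
#' @export
oversample <- function(dataset, seed = 1L) {
  check_all_stages_present(dataset$labels)
  set.seed(seed)
  M <- max(table(dataset$labels))
  idx <- sort(unlist(lapply(1:3, function(s) {
    pool <- which(dataset$labels == s)
    extra <- M - length(pool)
    c(pool, if (extra > 0) sample(pool, extra, replace = TRUE))
  })))
  dataset_subset(dataset, idx)
}

#' Two-step training plan
#'
#' Pretraining optimizes the feature extractor under a temporary per-epoch
#' softmax on a stage-balanced (undersampled) set; fine-tuning then trains
#' the whole network, scoring head included, at a smaller learning rate to
#' avoid overfitting.  The `"paper"` profile carries the published
#' full-scale settings (Adam, learning rates 1e-4 and 1e-6, batch sizes 100
#' and 10 epochs/sequences, 10 + 20 passes).  The `"desk"` profile keeps the
#' structure, batch sizes and pass counts but raises the learning rates to
#' 1e-3/1e-4: at desk scale a training run takes hundreds of optimizer steps
#' rather than millions, and 1e-6 cannot move a freshly initialized scoring
#' head off its random start.
#'
#' @param profile `"desk"` (default) or `"paper"`.
#' @param pretrain_epochs,finetune_epochs Passes over the training set.
#' @param pretrain_lr,finetune_lr Adam learning rates; the fine-tuning rate
#'   must be the smaller of the two.
#' @param pretrain_batch Epochs per pretraining step.
#' @param finetune_batch Sequences per fine-tuning step.
#' @param finetune_balancing `"none"` or `"oversample"` (sequence-level
#'   resampling toward stage balance).
#' @param grad_clip Global gradient-norm clip (`Inf` disables); guards the
#'   small-batch fine-tuning stage against divergence.
#' @return A `training_plan`.
#' @export
training_plan <- function(profile = c("desk", "paper"),
                          pretrain_epochs = 10, finetune_epochs = 20,
                          pretrain_lr = NULL, finetune_lr = NULL,
                          pretrain_batch = 100, finetune_batch = 10,
                          finetune_balancing = c("none", "oversample"),
                          grad_clip = 5) {
  profile <- match.arg(profile)
  finetune_balancing <- match.arg(finetune_balancing)
  pretrain_lr <- pretrain_lr %||% if (profile == "paper") 1e-4 else 1e-3
  finetune_lr <- finetune_lr %||% if (profile == "paper") 1e-6 else 1e-4
  stopifnot(pretrain_lr >= 0, finetune_lr >= 0,
            pretrain_epochs >= 0, finetune_epochs >= 0,
            pretrain_batch >= 1, finetune_batch >= 1)
  if (pretrain_lr > 0 && finetune_lr >= pretrain_lr) {
    abort("finetune_lr must be smaller than pretrain_lr (overfitting guard)")
  }
  structure(list(profile = profile,
                 pretrain = list(epochs = pretrain_epochs, lr = pretrain_lr,
                                 batch = pretrain_batch,
                                 balancing = "undersample"),
                 finetune = list(epochs = finetune_epochs, lr = finetune_lr,
                                 batch = finetune_batch,
                                 balancing = finetune_balancing),
                 optimizer = "adam", beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                 grad_clip = grad_clip),
            class = "training_plan")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, plan) {
  if (is.finite(plan$grad_clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gn > plan$grad_clip) {
      grads <- lapply(grads, function(g) g * (plan$grad_clip / gn))
    }
  }
  state$t <- state$t + 1L
  bc1 <- 1 - plan$beta1^state$t
  bc2 <- 1 - plan$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- plan$beta1 * state$m[[nm]] + (1 - plan$beta1) * g
    state$v[[nm]] <- plan$beta2 * state$v[[nm]] + (1 - plan$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + plan$eps)
  }
  list(params = params, state = state)
}

check_finite_loss <- function(loss, phase, step) {
  if (!is.finite(loss)) {
    abort(sprintf("training diverged: non-finite loss at %s step %d",
                  phase, step))
  }
}

check_dataset_for_model <- function(model, dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (nrow(dataset$eeg) != model$config$samples_per_epoch) {
    abort("dataset epoch length does not match the model configuration")
  }
}

# ---- Pretraining -----------------------------------------------------------

#' Pretrain the feature extractor
#'
#' Replaces the scoring head with a per-epoch softmax and optimizes the
#' convolutional extractor by backpropagation of the cross-entropy loss with
#' Adam, on a stage-balanced (undersampled) copy of the dataset.
#'
#' @param model A `sleep_model` with `variant = "pretrain_head"`.
#' @param dataset A [labeled_dataset()].
#' @param plan A [training_plan()].
#' @param seed Integer seed governing balancing, shuffling and dropout.
#' @return The trained model; `$history` holds one row per pass with the
#'   mean training loss.
#' @export
pretrain <- function(model, dataset, plan = training_plan(), seed = 1L) {
  stopifnot(inherits(model, "sleep_model"))
  if (model$config$variant != "pretrain_head") {
    abort("pretrain() needs a model with variant = 'pretrain_head'")
  }
  check_dataset_for_model(model, dataset)
  if (identical(plan$pretrain$balancing, "undersample")) {
    dataset <- undersample(dataset, seed = seed)
  }
  run_epoch_training(model, dataset, plan$pretrain, plan, seed,
                     phase = "pretrain", grad_fun = cpp_grad_pretrain)
}

# shared loop for the per-epoch heads (pretrain softmax / rescoring FC)
run_epoch_training <- function(model, dataset, stage_plan, plan, seed, phase,
                               grad_fun) {
  set.seed(seed + 1L)
  cfg <- cfg_cpp(model$config)
  params <- model$params
  state <- adam_init(params)
  n <- length(dataset$labels)
  history <- list()
  for (ep in seq_len(stage_plan$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / stage_plan$batch))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      drop_seed <- if (model$config$dropout_rate > 0) {
        sample.int(.Machine$integer.max - 1L, 1)
      } else 0
      res <- grad_fun(dataset$eeg[, idx, drop = FALSE],
                      dataset$emg[, idx, drop = FALSE],
                      dataset$labels[idx], params, cfg, drop_seed)
      check_finite_loss(res$loss, phase, bi)
      upd <- adam_step(params, res$grads, state, stage_plan$lr, plan)
      params <- upd$params
      state <- upd$state
      losses[bi] <- res$loss
    }
    history[[ep]] <- tibble(phase = phase, epoch = ep, loss = mean(losses))
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- bind_rows(model$history, bind_rows(history))
  model
}

# ---- Fine-tuning -----------------------------------------------------------

# Non-overlapping training sequences of `context` epochs per record,
# chunked from `offset` epochs into each record; remainders shorter than
# one context are dropped.  The offset is re-drawn every pass so an epoch
# is not frozen at one within-sequence position (fixed-phase truncation
# would always train bout transitions at the same truncated context).
# Returns a list of integer column-index vectors into the dataset.
finetune_sequences <- function(dataset, context, offset = 0L) {
  stopifnot(offset >= 0, offset < context)
  starts <- c(1L, head(dataset$record_end, -1) + 1L)
  ends <- dataset$record_end
  seqs <- list()
  for (r in seq_along(starts)) {
    nrec <- ends[r] - starts[r] + 1L - offset
    nseq <- nrec %/% context
    if (nseq < 1) next
    for (s in seq_len(nseq)) {
      a <- starts[r] + offset + (s - 1L) * context
      seqs[[length(seqs) + 1L]] <- a:(a + context - 1L)
    }
  }
  seqs
}

#' Fine-tune the full scoring network
#'
#' Transfers the pretrained extractor weights into a full-variant model and
#' optimizes all parameters with Adam at the (smaller) fine-tuning learning
#' rate.  Training batches are non-overlapping context-length sequences that
#' never span a record boundary; the cross-entropy is evaluated at every
#' sequence position, so each labeled epoch contributes once per pass.
#' With `finetune_balancing = "oversample"` sequences are resampled with
#' replacement each pass, weighted by the scarcity of the stages they
#' contain.
#'
#' @param model A `sleep_model` with `variant = "full"`.
#' @param extractor A pretrained `sleep_model` (any variant) whose branch
#'   weights are copied in, or `NULL` to fine-tune from `model`'s own
#'   initialization.
#' @param dataset A [labeled_dataset()].
#' @param plan A [training_plan()].
#' @param seed Integer seed.
#' @return The trained full model with appended `$history`.
#' @export
finetune <- function(model, extractor = NULL, dataset, plan = training_plan(),
                     seed = 1L) {
  stopifnot(inherits(model, "sleep_model"))
  if (model$config$variant != "full") {
    abort("finetune() needs a model with variant = 'full'")
  }
  check_dataset_for_model(model, dataset)
  if (!is.null(extractor)) {
    branch_names <- grep("^(nar|wid|emg)_", names(extractor$params), value = TRUE)
    model$params[branch_names] <- extractor$params[branch_names]
    model$history <- extractor$history
  }
  if (plan$finetune$epochs == 0) {
    return(model)
  }
  set.seed(seed + 2L)
  cfg <- cfg_cpp(model$config)
  context <- model$config$context
  if (length(finetune_sequences(dataset, context)) == 0) {
    abort(sprintf("no record holds a full %d-epoch training sequence", context))
  }
  params <- model$params
  state <- adam_init(params)
  history <- list()
  for (ep in seq_len(plan$finetune$epochs)) {
    # fresh chunking phase each pass (0 on the first, so a single pass sees
    # every record from its start)
    offset <- if (ep == 1) 0L else sample.int(context, 1) - 1L
    seqs <- finetune_sequences(dataset, context, offset)
    seq_weight <- if (plan$finetune$balancing == "oversample") {
      freq <- tabulate(dataset$labels, 3) / length(dataset$labels)
      vapply(seqs, function(ix) mean(1 / freq[dataset$labels[ix]]), numeric(1))
    }
    ord <- if (is.null(seq_weight)) {
      sample.int(length(seqs))
    } else {
      sample.int(length(seqs), replace = TRUE, prob = seq_weight)
    }
    batches <- split(ord, ceiling(seq_along(ord) / plan$finetune$batch))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      cols <- unlist(seqs[batches[[bi]]])
      drop_seed <- if (model$config$dropout_rate > 0) {
        sample.int(.Machine$integer.max - 1L, 1)
      } else 0
      res <- cpp_grad_full(dataset$eeg[, cols, drop = FALSE],
                           dataset$emg[, cols, drop = FALSE],
                           dataset$labels[cols], context, params, cfg,
                           drop_seed)
      check_finite_loss(res$loss, "finetune", bi)
      upd <- adam_step(params, res$grads, state, plan$finetune$lr, plan)
      params <- upd$params
      state <- upd$state
      losses[bi] <- res$loss
    }
    history[[ep]] <- tibble(phase = "finetune", epoch = ep, loss = mean(losses))
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- bind_rows(model$history, bind_rows(history))
  model
}

#' Train a sleep scorer end to end
#'
#' Convenience wrapper running the full two-step procedure: build the
#' labeled dataset, pretrain the extractor under a temporary softmax, then
#' fine-tune the full network.
#'
#' @param records,hypnograms Lists of training [signal_record()]s and
#'   matching [hypnogram()]s.
#' @param config A [sleep_model_config()] (variant is managed internally).
#' @param plan A [training_plan()].
#' @param seed Integer seed.
#' @param skip_pretrain Train the full network from scratch (documented
#'   deviation from the two-step recipe).
#' @return A trained full-variant `sleep_model`.
#' @export
train_sleep_model <- function(records, hypnograms, config,
                              plan = training_plan(), seed = 1L,
                              skip_pretrain = FALSE) {
  cfg_pre <- config; cfg_pre$variant <- "pretrain_head"
  cfg_full <- config; cfg_full$variant <- "full"
  ds <- labeled_dataset(records, hypnograms, config)
  extractor <- NULL
  if (!skip_pretrain) {
    pre <- sleep_model(cfg_pre, seed = seed)
    extractor <- pretrain(pre, ds, plan, seed = seed)
  }
  full <- sleep_model(cfg_full, seed = seed + 10L)
  finetune(full, extractor, ds, plan, seed = seed)
}
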