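#' Rescoring policy
#'
#' The main scorer tends to under-call the rare REM stage; most missed REM
#' epochs are labeled non-REM with low certainty.  The rescoring pass
#' therefore collects epochs labeled non-REM whose non-REM certainty is
#' strictly below the threshold and re-examines them with a context-free
#' model.
#'
#' @param trigger_label Stage whose low-certainty calls are re-examined.
#' @param certainty_threshold Strict upper bound on the trigger stage's
#'   certainty (default 0.95).
#' @return A `rescoring_policy`.
#' @export
rescoring_policy <- function(trigger_label = "NREM",
                             certainty_threshold = 0.95) {
  if (!(certainty_threshold > 0 && certainty_threshold <= 1)) {
    abort("certainty_threshold must be in (0, 1]")
  }
  structure(list(trigger_label = as.character(stage_factor(trigger_label)),
                 certainty_threshold = certainty_threshold),
            class = "rescoring_policy")
}

#' Select epochs eligible for rescoring
#'
#' Exactly the epochs whose predicted label equals the policy's trigger
#' stage and whose certainty for that stage is strictly below the threshold;
#' epochs with other labels are never selected regardless of certainty.
#'
#' @param predictions A prediction tibble from [predict.sleep_model()].
#' @param policy A [rescoring_policy()].
#' @return Integer vector of `epoch` indices (0-based, as in `predictions`).
#' @export
select_rescoring_candidates <- function(predictions,
                                        policy = rescoring_policy()) {
  pcol <- c(WAKE = "p_wake", NREM = "p_nrem", REM = "p_rem")[policy$trigger_label]
  sel <- as.character(predictions$stage) == policy$trigger_label &
    predictions[[pcol]] < policy$certainty_threshold
  as.integer(predictions$epoch[sel])
}

#' Train the rescoring model
#'
#' Scores the training records with the trained full model, collects the
#' policy's low-certainty non-REM epochs, and trains the recurrent-free
#' `rescoring` variant (FC path + softmax only) on those epochs with their
#' expert labels.  Because missed REM concentrates in this candidate set,
#' its class distribution is far less skewed than the full data's.  The
#' extractor starts from the full model's trained branch weights; training
#' uses the plan's pretraining settings (the head is learned from scratch).
#'
#' @param model A trained full-variant `sleep_model`.
#' @param dataset The training [labeled_dataset()].
#' @param plan A [training_plan()].
#' @param policy A [rescoring_policy()].
#' @param seed Integer seed.
#' @return A trained `rescoring`-variant `sleep_model`.
#' @export
train_rescoring_model <- function(model, dataset, plan = training_plan(),
                                  policy = rescoring_policy(), seed = 1L) {
  stopifnot(inherits(model, "sleep_model"))
  if (model$config$variant != "full") {
    abort("the rescoring model is derived from a trained full model")
  }
  check_dataset_for_model(model, dataset)
  cand <- dataset_candidates(model, dataset, policy)
  if (length(cand) == 0) {
    abort(paste("no rescoring candidates: every trigger-stage prediction is",
                "above the certainty threshold; consider raising it"),
          class = "sleepscorer_no_candidates")
  }
  sub <- dataset_subset(dataset, cand)
  cfg_r <- model$config
  cfg_r$variant <- "rescoring"
  rmodel <- sleep_model(cfg_r, seed = seed)
  branch_names <- grep("^(nar|wid|emg)_", names(model$params), value = TRUE)
  rmodel$params[branch_names] <- model$params[branch_names]
  rmodel <- run_epoch_training(rmodel, sub, plan$pretrain, plan, seed,
                               phase = "rescoring", grad_fun = cpp_grad_rescoring)
  attr(rmodel, "n_candidates") <- length(cand)
  attr(rmodel, "candidate_labels") <- sub$labels
  rmodel
}

# candidate dataset columns: predict per record, map scored epochs back to
# dataset columns
dataset_candidates <- function(model, dataset, policy) {
  starts <- c(1L, head(dataset$record_end, -1) + 1L)
  ends <- dataset$record_end
  cand <- integer(0)
  for (r in seq_along(starts)) {
    cols <- starts[r]:ends[r]
    es <- new_epoch_set(dataset$eeg[, cols, drop = FALSE],
                        dataset$emg[, cols, drop = FALSE],
                        dataset$sampling_rate, dataset$epoch_length,
                        dataset$record_id[starts[r]], preprocessed = TRUE,
                        normalized = dataset$normalized,
                        rms_mode = dataset$rms_mode)
    pred <- suppressWarnings(predict(model, es))
    sel <- select_rescoring_candidates(pred, policy)
    cand <- c(cand, starts[r] + sel)   # sel is 0-based within the record
  }
  cand
}

#' Apply the rescoring pass
#'
#' Re-examines the policy's candidate epochs with the rescoring model;
#' candidates take the rescoring model's label and certainties, every other
#' epoch is untouched.  A changelog of altered epochs is attached as the
#' `"changelog"` attribute (also returned by [rescoring_changelog()]).
#'
#' @param predictions Prediction tibble from the full model.
#' @param rescoring_model A trained `rescoring`-variant model.
#' @param epochs The preprocessed `epoch_set` the predictions came from.
#' @param policy A [rescoring_policy()].
#' @return The updated prediction tibble.
#' @export
apply_rescoring <- function(predictions, rescoring_model, epochs,
                            policy = rescoring_policy()) {
  stopifnot(inherits(rescoring_model, "sleep_model"))
  if (rescoring_model$config$variant != "rescoring") {
    abort("apply_rescoring() needs a rescoring-variant model")
  }
  cand <- select_rescoring_candidates(predictions, policy)
  changelog <- tibble(epoch = integer(0),
                      old_stage = character(0), new_stage = character(0),
                      old_certainty = numeric(0), new_certainty = numeric(0))
  if (length(cand) > 0) {
    if (any(cand + 1L > n_epochs(epochs))) {
      abort("prediction epochs misaligned with the epoch set")
    }
    sub <- epoch_subset(epochs, cand + 1L)
    feat <- model_features(rescoring_model, sub)
    probs <- head_probs(rescoring_model, feat)
    new_pred <- prediction_tibble(cand, probs)
    rows <- match(cand, predictions$epoch)
    changelog <- tibble(
      epoch = cand,
      old_stage = as.character(predictions$stage[rows]),
      new_stage = as.character(new_pred$stage),
      old_certainty = pmax(predictions$p_wake[rows], predictions$p_nrem[rows],
                           predictions$p_rem[rows]),
      new_certainty = pmax(new_pred$p_wake, new_pred$p_nrem, new_pred$p_rem))
    predictions$p_wake[rows] <- new_pred$p_wake
    predictions$p_nrem[rows] <- new_pred$p_nrem
    predictions$p_rem[rows] <- new_pred$p_rem
    predictions$stage[rows] <- new_pred$stage
  }
  attr(predictions, "changelog") <- changelog
  predictions
}

#' Changelog of the last rescoring pass
#' @param predictions Output of [apply_rescoring()].
#' @return Tibble of altered epochs (old/new stage and certainty).
#' @export
rescoring_changelog <- function(predictions) {
  attr(predictions, "changelog") %||%
    abort("no changelog attached; run apply_rescoring() first")
}
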