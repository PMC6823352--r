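#' Score a raw record end to end
#'
#' Preprocesses the record exactly as the model expects (RMS mode,
#' normalization, epoch length from the model's configuration), scores it,
#' and optionally runs the REM rescoring pass.
#'
#' @param model A trained full-variant `sleep_model`.
#' @param record A [signal_record()].
#' @param rescoring_model Optional trained rescoring-variant model.
#' @param policy A [rescoring_policy()] (used only with a rescoring model).
#' @return A prediction tibble (see [predict.sleep_model()]); with rescoring,
#'   the changelog is attached as attribute `"changelog"`.
#' @export
score_record <- function(model, record, rescoring_model = NULL,
                         policy = rescoring_policy()) {
  cfg <- model$config
  epochs <- preprocess_record(record, epoch_length = cfg$epoch_length,
                              mode = cfg$rms_mode, normalize = cfg$normalize)
  pred <- predict(model, epochs)
  if (!is.null(rescoring_model)) {
    pred <- apply_rescoring(pred, rescoring_model, epochs, policy)
  }
  pred
}

#' Convert predictions to a hypnogram
#'
#' @param predictions Prediction tibble from [predict.sleep_model()] or
#'   [score_record()].
#' @param record_id,epoch_length Metadata for the hypnogram; default to the
#'   prediction attributes.
#' @return A [hypnogram()] covering the scored epochs (record-edge epochs
#'   that received no prediction are absent; their indices are preserved in
#'   the `epoch` column).
#' @export
as_hypnogram <- function(predictions, record_id = NULL, epoch_length = 20) {
  h <- hypnogram(predictions$stage,
                 certainties = cbind(predictions$p_wake, predictions$p_nrem,
                                     predictions$p_rem),
                 record_id = record_id %||% attr(predictions, "record_id") %||%
                   "scored",
                 epoch_length = epoch_length)
  h$epoch <- as.integer(predictions$epoch)
  h
}

# hypnogram TSV including explicit "U" rows for unscored epochs
write_scored_tsv <- function(predictions, path, epoch_length = 20) {
  n <- attr(predictions, "n_epochs") %||% (max(predictions$epoch) + 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# record_id: %s",
                       attr(predictions, "record_id") %||% "scored"),
               sprintf("# epoch_length: %g", epoch_length),
               "epoch_index\tstage\tp_wake\tp_nrem\tp_rem"), con)
  rows <- match(0:(n - 1L), predictions$epoch)
  lines <- ifelse(is.na(rows),
                  sprintf("%d\tU\t\t\t", 0:(n - 1L)),
                  sprintf("%d\t%s\t%.6f\t%.6f\t%.6f", 0:(n - 1L),
                          STAGE_LETTERS[as.integer(predictions$stage[rows])],
                          predictions$p_wake[rows], predictions$p_nrem[rows],
                          predictions$p_rem[rows]))
  writeLines(lines, con)
  invisible(path)
}
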