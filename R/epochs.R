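#' Split a record into fixed-length epochs
#'
#' Cuts the record into consecutive non-overlapping epochs of
#' `epoch_length` seconds.  Epoch `i` (0-based) covers the half-open sample
#' interval `[i * rate * epoch_length, (i + 1) * rate * epoch_length)`;
#' trailing samples that do not fill a whole epoch are dropped.  A record
#' shorter than one epoch yields an empty epoch set (not an error).
#'
#' @param record A [signal_record()].
#' @param epoch_length Epoch duration in seconds.
#' @return An `epoch_set`: EEG and EMG sample matrices with one column per
#'   epoch, plus sampling metadata.
#' @examples
#' rec <- signal_record(rnorm(25100), rnorm(25100), 250)
#' split_epochs(rec, 20)  # 5 epochs; 100 samples dropped
#' @export
split_epochs <- function(record, epoch_length = 20) {
  stopifnot(inherits(record, "signal_record"), epoch_length > 0)
  L <- as.integer(round(record$sampling_rate * epoch_length))
  n <- length(record$eeg) %/% L
  take <- seq_len(n * L)
  new_epoch_set(
    eeg = matrix(record$eeg[take], nrow = L, ncol = n),
    emg = matrix(record$emg[take], nrow = L, ncol = n),
    sampling_rate = record$sampling_rate, epoch_length = epoch_length,
    record_id = record$record_id, preprocessed = FALSE, normalized = FALSE)
}

new_epoch_set <- function(eeg, emg, sampling_rate, epoch_length, record_id,
                          preprocessed, normalized, rms_mode = NULL) {
  structure(list(eeg = eeg, emg = emg,
                 sampling_rate = as.integer(sampling_rate),
                 epoch_length = epoch_length, record_id = record_id,
                 preprocessed = preprocessed, normalized = normalized,
                 rms_mode = rms_mode),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> '%s': %d epochs of %gs at %d Hz (%s%s)\n",
              x$record_id, n_epochs(x), x$epoch_length, x$sampling_rate,
              if (x$preprocessed) paste0("preprocessed, EMG ", x$rms_mode)
              else "raw",
              if (isTRUE(x$normalized)) ", z-scored" else ""))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(epochs) ncol(epochs$eeg)

#' @export
as_tibble.epoch_set <- function(x, ...) {
  n <- n_epochs(x)
  L <- nrow(x$eeg)
  tibble(epoch = rep(seq_len(n) - 1L, each = L),
         sample = rep(seq_len(L) - 1L, times = n),
         eeg = as.vector(x$eeg), emg = as.vector(x$emg))
}

# subset columns (epochs) of an epoch_set
epoch_subset <- function(epochs, idx) {
  out <- epochs
  out$eeg <- epochs$eeg[, idx, drop = FALSE]
  out$emg <- epochs$emg[, idx, drop = FALSE]
  out
}
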