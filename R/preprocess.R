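#' Moving root-mean-square filter
#'
#' Emphasizes EMG amplitude by replacing each sample with an RMS statistic of
#' the trailing one-second window (the `sampling_rate` samples before `t`).
#' Two flavours are provided:
#'
#' * `mode = "paper"` (default): `y_t = 1/(Fs - 1) * sqrt(sum_{i=1..Fs} x_{t-i}^2)`,
#'   the published form, with the `1/(Fs - 1)` factor outside the square
#'   root.  Note this is not unit-preserving: a constant signal `c` maps to
#'   `c * sqrt(Fs) / (Fs - 1)`.
#' * `mode = "standard"`: textbook RMS `sqrt(mean(x_{t-i}^2))`, which maps a
#'   constant `c` to `c`.
#'
#' The two modes differ only by a constant factor
#' (`paper / standard = sqrt(Fs) / (Fs - 1)`), which the tests pin down
#' numerically.  The first second is warmed up by reflect-padding the first
#' `Fs` samples, avoiding a spurious ramp at the start of the record.
#'
#' @param x Numeric signal (µV); must be finite and at least one filter
#'   width (`sampling_rate` samples) long.
#' @param sampling_rate Samples per second (>= 2); also the filter width.
#' @param mode `"paper"` or `"standard"`.
#' @return Non-negative numeric vector, same length as `x`.
#' @examples
#' moving_rms(rep(2, 12), sampling_rate = 4, mode = "standard")  # all 2
#' @export
moving_rms <- function(x, sampling_rate, mode = c("paper", "standard")) {
  mode <- match.arg(mode)
  fs <- as.integer(round(sampling_rate))
  if (fs < 2) abort("sampling_rate must be at least 2")
  if (length(x) < fs) {
    abort(sprintf("signal (%d samples) shorter than one filter width (%d)",
                  length(x), fs))
  }
  if (!all(is.finite(x))) abort("signal contains non-finite samples")
  xp <- c(rev(x[seq_len(fs)]), x)          # reflect-pad the first second
  cs <- cumsum(xp^2)
  # window for output t: padded positions t .. t+fs-1 (the fs samples before
  # original sample t)
  n <- length(x)
  upper <- cs[seq_len(n) + fs - 1L]
  lower <- c(0, cs)[seq_len(n)]
  ssq <- pmax(upper - lower, 0)
  if (mode == "paper") sqrt(ssq) / (fs - 1) else sqrt(ssq / fs)
}

#' Preprocess a record for scoring
#'
#' EEG epochs pass through untouched (no spectral preprocessing, so the
#' convolutional extractor sees the raw waveform); the EMG trace is
#' moving-RMS filtered over the whole record (see [moving_rms()]) before
#' epoching.  Optionally both channels are z-scored per record, which bounds
#' the dynamic range across animals with different electrode gains; note the
#' z-scored RMS-EMG is no longer non-negative.
#'
#' @param record A [signal_record()].
#' @param epoch_length Epoch duration in seconds.
#' @param mode Moving-RMS flavour, see [moving_rms()].
#' @param normalize Z-score each channel over the record.
#' @return An `epoch_set` with `preprocessed = TRUE`; the `emg` matrix holds
#'   the filtered (and optionally normalized) trace.
#' @export
preprocess_record <- function(record, epoch_length = 20,
                              mode = c("paper", "standard"),
                              normalize = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "signal_record"))
  emg_rms <- moving_rms(record$emg, record$sampling_rate, mode = mode)
  filtered <- signal_record(record$eeg, emg_rms,
                            sampling_rate = record$sampling_rate,
                            record_id = record$record_id)
  es <- split_epochs(filtered, epoch_length)
  es$preprocessed <- TRUE
  es$rms_mode <- mode
  if (normalize) {
    zs <- function(m) {
      s <- stats::sd(m)
      if (s > 0) (m - mean(m)) / s else m - mean(m)
    }
    es$eeg <- zs(es$eeg)
    es$emg <- zs(es$emg)
    es$normalized <- TRUE
  }
  es
}

#' Enumerate context windows over preprocessed epochs
#'
#' The full scoring head reads `context` consecutive epochs and labels the
#' center one, so only epochs with `(context - 1) / 2` neighbours on both
#' sides are scorable; windows slide one epoch at a time and edge epochs are
#' reported as unscorable rather than padded.
#'
#' @param epochs An `epoch_set` (or anything with an epoch count via
#'   [n_epochs()]).
#' @param context Odd window length in epochs.
#' @return A tibble with one row per window: `window` (1-based), `start_epoch`
#'   and `target_epoch` (0-based).  Attributes `n_epochs` and `unscorable`
#'   (0-based indices of epochs no window targets).  Fewer epochs than
#'   `context` yields zero rows with a warning.
#' @examples
#' es <- split_epochs(signal_record(rnorm(4000), rnorm(4000), 10), 20)
#' build_context_windows(es, context = 5)
#' @export
build_context_windows <- function(epochs, context = 25) {
  stopifnot(context %% 2 == 1, context >= 1)
  n <- if (inherits(epochs, "epoch_set")) n_epochs(epochs) else as.integer(epochs)
  half <- context %/% 2
  if (n < context) {
    warn(sprintf("only %d epochs but the context window needs %d; no windows",
                 n, context))
    out <- tibble(window = integer(0), start_epoch = integer(0),
                  target_epoch = integer(0))
    attr(out, "n_epochs") <- n
    attr(out, "unscorable") <- seq_len(n) - 1L
    return(out)
  }
  starts <- 0:(n - context)
  out <- tibble(window = seq_along(starts), start_epoch = starts,
                target_epoch = starts + half)
  attr(out, "n_epochs") <- n
  attr(out, "unscorable") <- setdiff(seq_len(n) - 1L, out$target_epoch)
  out
}
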