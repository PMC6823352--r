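#' Create a paired EEG/EMG signal record
#'
#' A signal record holds one animal's paired electroencephalogram and
#' electromyogram traces (microvolts) at a common sampling rate.  Both traces
#' must have equal length.
#'
#' @param eeg,emg Numeric vectors of samples in microvolts.
#' @param sampling_rate Samples per second (Hz, positive).
#' @param record_id Identifier carried through epoching, scoring and output
#'   files.
#' @param start_time Optional `POSIXct` recording start.
#' @return A `signal_record` object.
#' @examples
#' rec <- signal_record(rnorm(5000), rnorm(5000), sampling_rate = 250)
#' rec
#' @export
signal_record <- function(eeg, emg, sampling_rate = 250,
                          record_id = "record", start_time = NULL) {
  if (!is.numeric(eeg) || !is.numeric(emg)) {
    abort("eeg and emg must be numeric vectors")
  }
  if (length(eeg) != length(emg)) {
    abort(sprintf("channel length mismatch: eeg has %d samples, emg has %d",
                  length(eeg), length(emg)))
  }
  if (length(eeg) == 0) abort("record must contain at least one sample")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    abort("sampling_rate must be a positive number")
  }
  structure(list(record_id = as.character(record_id),
                 eeg = as.numeric(eeg), emg = as.numeric(emg),
                 sampling_rate = as.integer(round(sampling_rate)),
                 start_time = start_time),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> '%s': %d samples at %d Hz (%.1f s)\n",
              x$record_id, length(x$eeg), x$sampling_rate,
              record_duration(x)))
  invisible(x)
}

#' Record duration in seconds
#' @param record A `signal_record`.
#' @return Duration in seconds.
#' @export
record_duration <- function(record) {
  length(record$eeg) / record$sampling_rate
}

#' @export
as_tibble.signal_record <- function(x, ...) {
  tibble(time = (seq_along(x$eeg) - 1) / x$sampling_rate,
         eeg = x$eeg, emg = x$emg)
}

#' Read a paired EEG/EMG record from disk
#'
#' Supports European Data Format (EDF) and a plain CSV dialect with header
#' `eeg,emg` plus either a JSON sidecar (`<path>.meta.json`, written by
#' [write_signal_record()]) or an explicit `sampling_rate`.  EDF channels are
#' picked as the first label containing "EEG"/"EMG" case-insensitively unless
#' named explicitly.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param sampling_rate Required for CSV files without a sidecar.
#' @param record_id Overrides the identifier stored in the container.
#' @param eeg_channel,emg_channel Explicit EDF channel labels.
#' @return A [signal_record()].
#' @export
read_signal_record <- function(path, format = c("auto", "edf", "csv"),
                               sampling_rate = NULL, record_id = NULL,
                               eeg_channel = NULL, emg_channel = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "edf") {
    read_edf_record(path, record_id = record_id,
                    eeg_channel = eeg_channel, emg_channel = emg_channel)
  } else {
    read_csv_record(path, sampling_rate = sampling_rate, record_id = record_id)
  }
}

#' Write a paired EEG/EMG record to disk
#'
#' CSV round-trips exactly (shortest round-trip decimal representation); EDF
#' quantizes to 16 bits over the declared physical range, so a round-trip
#' agrees within one quantization step.
#'
#' @param record A [signal_record()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param physical_range Symmetric full-scale range in µV for EDF; defaults
#'   to the data's absolute maximum.
#' @return The path, invisibly.
#' @export
write_signal_record <- function(record, path, format = c("auto", "edf", "csv"),
                                physical_range = NULL) {
  stopifnot(inherits(record, "signal_record"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") {
    write_edf_record(record, path, physical_range = physical_range)
  } else {
    write_csv_record(record, path)
  }
  invisible(path)
}

read_csv_record <- function(path, sampling_rate = NULL, record_id = NULL) {
  dat <- utils::read.csv(path)
  if (!all(c("eeg", "emg") %in% names(dat))) {
    missing <- setdiff(c("eeg", "emg"), names(dat))
    abort(sprintf("channel not found: %s (available: %s)",
                  paste(missing, collapse = ", "),
                  paste(names(dat), collapse = ", ")))
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  rate <- sampling_rate %||% meta$sampling_rate
  if (is.null(rate)) {
    abort("sampling_rate must be given (no sidecar metadata found)")
  }
  signal_record(dat$eeg, dat$emg, sampling_rate = rate,
                record_id = record_id %||% meta$record_id %||%
                  sub("\\.csv$", "", basename(path)))
}

write_csv_record <- function(record, path) {
  # format() with 17 significant digits guarantees an exact decimal
  # round-trip for doubles
  df <- data.frame(eeg = record$eeg, emg = record$emg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("eeg,emg", con)
  writeLines(paste(format(record$eeg, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   format(record$emg, digits = 17, trim = TRUE,
                          scientific = TRUE), sep = ","), con)
  jsonlite::write_json(list(record_id = record$record_id,
                            sampling_rate = record$sampling_rate),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
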