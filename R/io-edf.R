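# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of little-endian 16-bit integers, one contiguous block per signal
# per record.  Digital values map linearly onto the declared physical range,
# so amplitudes are quantized to (phys_max - phys_min) / (dig_max - dig_min).
# The writer emits a single data record holding the whole recording, which
# any conforming reader (and this one) accepts.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) abort(sprintf("EDF header field too long: '%s'", x))
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = width - 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  pad_field(s, width)
}

write_edf_record <- function(record, path, physical_range = NULL) {
  n <- length(record$eeg)
  if (n == 0) abort("refusing to write a zero-length record")
  pr <- physical_range %||% max(abs(c(record$eeg, record$emg)), 1e-6)
  dig_min <- -32768; dig_max <- 32767
  to_dig <- function(x) {
    d <- round((x - (-pr)) / (2 * pr) * (dig_max - dig_min) + dig_min)
    as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  ns <- 2L
  header_bytes <- 256L + 256L * ns
  duration <- n / record$sampling_rate

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  put(pad_field("0", 8))                       # version
  put(pad_field(record$record_id, 80))         # patient id
  put(pad_field("sleepscorer", 80))            # recording id
  put(pad_field("01.01.00", 8))                # start date
  put(pad_field("00.00.00", 8))                # start time
  put(pad_field(header_bytes, 8))
  put(pad_field("", 44))
  put(pad_field(1, 8))                         # number of data records
  put(edf_num(duration, 8))
  put(pad_field(ns, 4))
  labels <- c("EEG", "EMG")
  for (lab in labels) put(pad_field(lab, 16))
  for (i in 1:ns) put(pad_field("", 80))       # transducer
  for (i in 1:ns) put(pad_field("uV", 8))
  for (i in 1:ns) put(edf_num(-pr, 8))
  for (i in 1:ns) put(edf_num(pr, 8))
  for (i in 1:ns) put(pad_field(dig_min, 8))
  for (i in 1:ns) put(pad_field(dig_max, 8))
  for (i in 1:ns) put(pad_field("", 80))       # prefiltering
  for (i in 1:ns) put(pad_field(n, 8))         # samples per record
  for (i in 1:ns) put(pad_field("", 32))
  writeBin(to_dig(record$eeg), con, size = 2, endian = "little")
  writeBin(to_dig(record$emg), con, size = 2, endian = "little")
  invisible(path)
}

read_edf_record <- function(path, record_id = NULL,
                            eeg_channel = NULL, emg_channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  getf <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  getf(8)                       # version
  patient <- getf(80)
  getf(80); getf(8); getf(8)    # recording id, date, time
  getf(8)                       # header bytes
  getf(44)
  n_rec <- as.integer(getf(8))
  duration <- as.numeric(getf(8))
  ns <- as.integer(getf(4))
  if (is.na(ns) || ns < 1) abort("malformed EDF header")
  labels <- vapply(1:ns, function(i) getf(16), character(1))
  for (i in 1:ns) getf(80)
  for (i in 1:ns) getf(8)       # physical dimension
  pmin_ <- vapply(1:ns, function(i) as.numeric(getf(8)), numeric(1))
  pmax_ <- vapply(1:ns, function(i) as.numeric(getf(8)), numeric(1))
  dmin_ <- vapply(1:ns, function(i) as.numeric(getf(8)), numeric(1))
  dmax_ <- vapply(1:ns, function(i) as.numeric(getf(8)), numeric(1))
  for (i in 1:ns) getf(80)
  spr <- vapply(1:ns, function(i) as.integer(getf(8)), integer(1))
  for (i in 1:ns) getf(32)

  pick <- function(want, explicit) {
    if (!is.null(explicit)) {
      i <- which(labels == explicit)
      if (length(i) == 0) {
        abort(sprintf("channel not found: '%s' (available: %s)",
                      explicit, paste(labels, collapse = ", ")))
      }
      return(i[1])
    }
    i <- grep(want, labels, ignore.case = TRUE)
    if (length(i) == 0) {
      abort(sprintf("channel not found: no label contains '%s' (available: %s)",
                    want, paste(labels, collapse = ", ")))
    }
    i[1]
  }
  i_eeg <- pick("EEG", eeg_channel)
  i_emg <- pick("EMG", emg_channel)

  chunks <- vector("list", ns)
  for (i in 1:ns) chunks[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in 1:ns) {
      chunks[[i]][[r]] <- readBin(con, "integer", n = spr[i], size = 2,
                                  signed = TRUE, endian = "little")
    }
  }
  to_phys <- function(i) {
    d <- unlist(chunks[[i]], use.names = FALSE)
    pmin_[i] + (d - dmin_[i]) / (dmax_[i] - dmin_[i]) * (pmax_[i] - pmin_[i])
  }
  eeg <- to_phys(i_eeg)
  emg <- to_phys(i_emg)
  if (length(eeg) != length(emg)) {
    abort("malformed EDF: EEG and EMG channels have different lengths")
  }
  rate <- spr[i_eeg] * n_rec / (duration * n_rec)
  signal_record(eeg, emg, sampling_rate = rate,
                record_id = record_id %||%
                  (if (nzchar(patient)) patient else basename(path)))
}

#' Quantization step of an EDF encoding
#'
#' The worst-case amplitude error of an EDF round-trip is half this step.
#'
#' @param physical_range Symmetric full-scale range in µV.
#' @return Step size in µV between adjacent 16-bit digital values.
#' @export
edf_quantization_step <- function(physical_range) {
  2 * physical_range / (32767 - (-32768))
}
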