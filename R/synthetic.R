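#' Stage signature parameters for synthetic polysomnography
#'
#' Describes, per vigilance stage, which EEG frequency bands carry power and
#' how large the EEG and EMG envelopes are.  Defaults encode the classic
#' mouse signatures: WAKE mixes broadband EEG (with an active-wake theta
#' component) and large EMG; non-REM is delta-dominant (1-4 Hz) with the
#' highest EEG amplitude and reduced EMG; REM is theta-dominant (6-9 Hz)
#' with near-total muscle atonia.  Band weights are relative powers.
#' Lognormal epoch-to-epoch amplitude jitter and a per-record gain emulate
#' within-animal variability and electrode/gain differences between animals.
#'
#' Amplitudes are in µV but are internally consistent rather than calibrated
#' to any real acquisition chain.
#'
#' @param wake,nrem,rem Per-stage lists with elements `bands` (list of
#'   `list(band = c(lo, hi), weight = w)`), `eeg_scale` and `emg_scale` (µV).
#' @param amplitude_jitter_sd Lognormal sigma of per-epoch amplitude jitter.
#' @param record_gain_sd Lognormal sigma of the per-record, per-channel gain.
#' @param emg_band EMG broadband support (Hz); the upper edge is clipped to
#'   the Nyquist frequency at synthesis time.
#' @return A `stage_signature_params` object.
#' @export
stage_signature_params <- function(
    wake = list(bands = list(list(band = c(1, 30), weight = 1),
                             list(band = c(6, 9), weight = 0.8)),
                eeg_scale = 40, emg_scale = 60),
    nrem = list(bands = list(list(band = c(1, 4), weight = 1),
                             list(band = c(1, 30), weight = 0.3)),
                eeg_scale = 80, emg_scale = 20),
    rem = list(bands = list(list(band = c(6, 9), weight = 1),
                            list(band = c(1, 30), weight = 0.25)),
               eeg_scale = 45, emg_scale = 5),
    amplitude_jitter_sd = 0.25, record_gain_sd = 0.15,
    emg_band = c(20, 100)) {
  stages <- list(WAKE = wake, NREM = nrem, REM = rem)
  for (nm in names(stages)) {
    s <- stages[[nm]]
    w <- vapply(s$bands, function(b) b$weight, numeric(1))
    if (any(w < 0) || !any(w > 0)) {
      abort(sprintf("%s: band weights must be non-negative with at least one positive", nm))
    }
    if (s$eeg_scale < 0 || s$emg_scale < 0) {
      abort(sprintf("%s: amplitude scales must be non-negative", nm))
    }
  }
  scales_pos <- all(vapply(stages, function(s) s$emg_scale, numeric(1)) > 0)
  if (scales_pos) {
    if (!(wake$emg_scale > nrem$emg_scale && nrem$emg_scale > rem$emg_scale)) {
      abort("EMG amplitude ordering must satisfy WAKE > NREM > REM")
    }
    if (!(nrem$eeg_scale > wake$eeg_scale)) {
      abort("EEG amplitude must be larger in NREM than in WAKE")
    }
  }
  structure(c(stages, list(amplitude_jitter_sd = amplitude_jitter_sd,
                           record_gain_sd = record_gain_sd,
                           emg_band = emg_band)),
            class = "stage_signature_params")
}

# Per-epoch stage-transition matrix whose stationary distribution is exactly
# the published stage prevalence (49.7% WAKE, 45.4% non-REM, 4.9% REM),
# with WAKE -> REM forbidden and a REM self-transition of 0.75 (mean bout
# 80 s at 20-s epochs).  Rows/cols: WAKE, NREM, REM.
default_transition_matrix <- function() {
  m <- matrix(c(0.95,                0.05,               0,
                0.03314977973568282, 0.93986784140969170, 0.02698237885462555,
                0.20,                0.05,               0.75),
              nrow = 3, byrow = TRUE,
              dimnames = list(STAGE_LEVELS, STAGE_LEVELS))
  m / rowSums(m)
}

#' Markov model of sleep-stage bout dynamics
#'
#' @param transition_matrix Row-stochastic 3x3 matrix of per-epoch transition
#'   probabilities (rows/cols ordered WAKE, NREM, REM).  The default is tuned
#'   so its stationary distribution matches the published stage prevalence
#'   (49.7/45.4/4.9%) and forbids WAKE -> REM, the transition that does not
#'   occur in healthy mice.
#' @param initial_distribution Starting-stage probabilities; defaults to the
#'   stationary distribution of the matrix.
#' @return A `transition_model`.
#' @export
transition_model <- function(transition_matrix = NULL,
                             initial_distribution = NULL) {
  P <- transition_matrix %||% default_transition_matrix()
  P <- as.matrix(P)
  if (!all(dim(P) == c(3, 3))) abort("transition matrix must be 3x3")
  if (any(P < 0)) abort("transition probabilities must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-9)) {
    abort("transition matrix rows must sum to 1 (tolerance 1e-9)")
  }
  dimnames(P) <- list(STAGE_LEVELS, STAGE_LEVELS)
  init <- initial_distribution %||% stationary_distribution(P)
  if (length(init) != 3 || any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    abort("initial distribution must be a probability 3-vector")
  }
  structure(list(transition_matrix = P,
                 initial_distribution = setNames(as.numeric(init), STAGE_LEVELS)),
            class = "transition_model")
}

#' Stationary distribution of a stochastic matrix
#' @param P Row-stochastic matrix.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  setNames(v / sum(v), rownames(P))
}

#' Sample a hypnogram from a transition model
#'
#' Draws a Markov-chain stage sequence; transitions with probability zero in
#' the matrix can never occur, so structural rules (no WAKE -> REM) are
#' conserved by construction.
#'
#' @param model A [transition_model()].
#' @param n_epochs Number of epochs (>= 1).
#' @param seed Integer seed; the sequence is fully reproducible.
#' @param record_id,epoch_length Passed to [hypnogram()].
#' @return A [hypnogram()].
#' @export
sample_hypnogram <- function(model, n_epochs, seed = 1L,
                             record_id = "synthetic", epoch_length = 20) {
  stopifnot(inherits(model, "transition_model"), n_epochs >= 1)
  set.seed(seed)
  P <- model$transition_matrix
  s <- integer(n_epochs)
  s[1] <- sample.int(3, 1, prob = model$initial_distribution)
  if (n_epochs > 1) {
    u <- runif(n_epochs - 1)
    cum <- t(apply(P, 1, cumsum))
    for (t in 2:n_epochs) {
      s[t] <- findInterval(u[t - 1], cum[s[t - 1], ]) + 1L
    }
  }
  hypnogram(s, record_id = record_id, epoch_length = epoch_length)
}

# Unit-variance Gaussian noise restricted to [lo, hi] Hz via FFT masking.
band_noise <- function(n, rate, lo, hi) {
  z <- rnorm(n)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)                  # two-sided frequency axis
  keep <- f >= lo & f <= hi
  if (!any(keep)) return(numeric(n))
  X <- fft(z)
  X[!keep] <- 0
  x <- Re(fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Synthesize an EEG/EMG record from a hypnogram
#'
#' Each epoch is stationary filtered Gaussian noise: the EEG is a sum of
#' band-limited components weighted by the target stage's band powers and
#' scaled to the stage's EEG amplitude; the EMG is broadband noise at the
#' stage's EMG amplitude.  Per-epoch lognormal jitter and a per-record gain
#' add realistic amplitude variability.  This emulates the visual spectral
#' and amplitude structure of the three stages without claiming
#' physiological microstructure (no spindles or phasic twitches).
#'
#' @param hypnogram A [hypnogram()] giving the ground-truth stages.
#' @param params A [stage_signature_params()].
#' @param sampling_rate Samples per second.
#' @param seed Integer seed; synthesis is fully reproducible.
#' @param record_id Defaults to the hypnogram's record id.
#' @return A [signal_record()] of `n_epochs * epoch_length * sampling_rate`
#'   samples.
#' @export
synthesize_record <- function(hypnogram, params = stage_signature_params(),
                              sampling_rate = 250, seed = 1L,
                              record_id = NULL) {
  stopifnot(inherits(hypnogram, "hypnogram"),
            inherits(params, "stage_signature_params"))
  set.seed(seed)
  rate <- as.integer(sampling_rate)
  epoch_length <- attr(hypnogram, "epoch_length") %||% 20
  L <- as.integer(round(rate * epoch_length))
  stages <- as.integer(hypnogram$stage)
  n <- length(stages)
  nyq <- rate / 2
  emg_lo <- min(params$emg_band[1], nyq * 0.4)
  emg_hi <- min(params$emg_band[2], nyq * 0.98)

  gain_eeg <- exp(rnorm(1, 0, params$record_gain_sd))
  gain_emg <- exp(rnorm(1, 0, params$record_gain_sd))

  eeg <- matrix(0, L, n)
  emg <- matrix(0, L, n)
  for (i in seq_len(n)) {
    sig <- params[[STAGE_LEVELS[stages[i]]]]
    w <- vapply(sig$bands, function(b) b$weight, numeric(1))
    x <- numeric(L)
    for (j in seq_along(sig$bands)) {
      if (w[j] <= 0) next
      b <- sig$bands[[j]]$band
      x <- x + sqrt(w[j]) * band_noise(L, rate, b[1], min(b[2], nyq * 0.98))
    }
    tot <- sqrt(sum(w))
    if (tot > 0) x <- x / tot
    jit_e <- exp(rnorm(1, 0, params$amplitude_jitter_sd))
    jit_m <- exp(rnorm(1, 0, params$amplitude_jitter_sd))
    eeg[, i] <- sig$eeg_scale * gain_eeg * jit_e * x
    emg[, i] <- sig$emg_scale * gain_emg * jit_m *
      band_noise(L, rate, emg_lo, emg_hi)
  }
  signal_record(as.vector(eeg), as.vector(emg), sampling_rate = rate,
                record_id = record_id %||% attr(hypnogram, "record_id"))
}

#' Noise specification for synthetic records
#'
#' Models the contamination seen in real mouse recordings: Poisson-scheduled
#' low-frequency motion-artifact bursts (0.5-2 Hz, the band that mimics
#' delta activity), continuous mains hum, and leakage of the EMG into the
#' EEG electrode.
#'
#' @param burst_rate Motion-artifact bursts per hour.
#' @param burst_band Burst frequency band in Hz.
#' @param burst_amplitude Burst envelope amplitude (µV).
#' @param burst_duration Burst length in seconds.
#' @param mains_frequency Mains hum frequency (50 or 60 Hz).
#' @param mains_amplitude Hum amplitude (µV) added to the EEG.
#' @param emg_mixing Fraction of the EMG trace mixed into the EEG.
#' @return A `noise_spec`.
#' @export
noise_spec <- function(burst_rate = 10, burst_band = c(0.5, 2),
                       burst_amplitude = 80, burst_duration = 2,
                       mains_frequency = 50, mains_amplitude = 20,
                       emg_mixing = 0.15) {
  stopifnot(burst_rate >= 0, burst_amplitude >= 0, burst_duration > 0,
            mains_amplitude >= 0, emg_mixing >= 0)
  structure(list(burst_rate = burst_rate, burst_band = burst_band,
                 burst_amplitude = burst_amplitude,
                 burst_duration = burst_duration,
                 mains_frequency = mains_frequency,
                 mains_amplitude = mains_amplitude,
                 emg_mixing = emg_mixing),
            class = "noise_spec")
}

#' Inject noise into a record
#'
#' Adds the contamination described by a [noise_spec()] to the EEG channel:
#' Hann-windowed band-limited artifact bursts at Poisson-distributed times,
#' a continuous mains sinusoid, and a scaled copy of the EMG.  An all-zero
#' spec returns the record unchanged.
#'
#' @param record A [signal_record()].
#' @param spec A [noise_spec()].
#' @param seed Integer seed.
#' @return A [signal_record()] of identical length.
#' @export
inject_noise <- function(record, spec, seed = 1L) {
  stopifnot(inherits(record, "signal_record"), inherits(spec, "noise_spec"))
  if (spec$burst_amplitude == 0 && spec$mains_amplitude == 0 &&
      spec$emg_mixing == 0) {
    return(record)
  }
  set.seed(seed)
  rate <- record$sampling_rate
  n <- length(record$eeg)
  eeg <- record$eeg
  hours <- n / rate / 3600

  if (spec$burst_amplitude > 0 && spec$burst_rate > 0) {
    n_bursts <- stats::rpois(1, spec$burst_rate * hours)
    blen <- as.integer(round(spec$burst_duration * rate))
    if (n_bursts > 0 && blen >= 2 && blen <= n) {
      env <- 0.5 * (1 - cos(2 * pi * seq_len(blen) / (blen + 1)))
      starts <- sample.int(n - blen + 1L, n_bursts, replace = TRUE)
      for (s in starts) {
        idx <- s:(s + blen - 1L)
        eeg[idx] <- eeg[idx] + spec$burst_amplitude * env *
          band_noise(blen, rate, spec$burst_band[1], spec$burst_band[2])
      }
      attr(eeg, "n_bursts") <- n_bursts
    }
  }
  if (spec$mains_amplitude > 0) {
    t <- (seq_len(n) - 1) / rate
    eeg <- eeg + spec$mains_amplitude * sin(2 * pi * spec$mains_frequency * t)
  }
  if (spec$emg_mixing > 0) {
    eeg <- eeg + spec$emg_mixing * record$emg
  }
  out <- signal_record(as.numeric(eeg), record$emg, sampling_rate = rate,
                       record_id = record$record_id)
  attr(out, "n_bursts") <- attr(eeg, "n_bursts")
  out
}

#' Generate a synthetic dataset of records with ground truth
#'
#' Draws independent seeded hypnograms and records; a stated fraction of the
#' records additionally receives noise injection (`round(n * fraction)`
#' records, at least one when the fraction is positive).  With `dir` set,
#' records (CSV or EDF), hypnogram TSVs and a manifest TSV are written.
#'
#' @param n_records Number of records (>= 1).
#' @param epochs_per_record Epochs per record.
#' @param params A [stage_signature_params()].
#' @param transitions A [transition_model()].
#' @param noise A [noise_spec()] applied to the noisy fraction.
#' @param noise_fraction Fraction of records receiving noise.
#' @param seed Master seed; all per-record seeds derive from it.
#' @param sampling_rate,epoch_length Signal geometry.
#' @param dir Optional output directory.
#' @param format `"csv"` or `"edf"` when writing.
#' @return A manifest tibble with columns `record_id`, `seed`, `noisy` and
#'   (when `dir` is `NULL`) list-columns `record` and `hypnogram`.
#' @export
make_dataset <- function(n_records, epochs_per_record,
                         params = stage_signature_params(),
                         transitions = transition_model(),
                         noise = noise_spec(), noise_fraction = 0,
                         seed = 1L, sampling_rate = 250, epoch_length = 20,
                         dir = NULL, format = c("csv", "edf")) {
  stopifnot(n_records >= 1, epochs_per_record >= 1,
            noise_fraction >= 0, noise_fraction <= 1)
  format <- match.arg(format)
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_records),
                      ncol = 3)
  n_noisy <- if (noise_fraction > 0) {
    max(1L, as.integer(round(n_records * noise_fraction)))
  } else 0L
  noisy <- rep(FALSE, n_records)
  if (n_noisy > 0) noisy[sample.int(n_records, n_noisy)] <- TRUE

  ids <- sprintf("rec%03d", seq_len(n_records))
  records <- vector("list", n_records)
  hyps <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    h <- sample_hypnogram(transitions, epochs_per_record, seed = sub_seeds[i, 1],
                          record_id = ids[i], epoch_length = epoch_length)
    r <- synthesize_record(h, params, sampling_rate = sampling_rate,
                           seed = sub_seeds[i, 2])
    if (noisy[i]) r <- inject_noise(r, noise, seed = sub_seeds[i, 3])
    records[[i]] <- r
    hyps[[i]] <- h
  }
  manifest <- tibble(record_id = ids, seed = sub_seeds[, 1], noisy = noisy)
  if (is.null(dir)) {
    manifest$record <- records
    manifest$hypnogram <- hyps
  } else {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (format == "csv") ".csv" else ".edf"
    manifest$signal_file <- paste0(ids, ext)
    manifest$hypnogram_file <- paste0(ids, ".hyp.tsv")
    for (i in seq_len(n_records)) {
      write_signal_record(records[[i]], file.path(dir, manifest$signal_file[i]),
                          format = format)
      write_hypnogram(hyps[[i]], file.path(dir, manifest$hypnogram_file[i]))
    }
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  manifest
}
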