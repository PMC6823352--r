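#' Hand-crafted spectral features for the random-forest baseline
#'
#' Converts each raw epoch into the six classic features: summed absolute
#' voltages `p_eeg` and `p_emg` over all epoch samples, and per-integer-Hz
#' periodogram band powers -- EEG 1-30 Hz (`w`, broadband), 1-6 Hz (`d`,
#' delta), 7-11 Hz (`t`, theta) and EMG 30-100 Hz (`e`, muscle band), all
#' inclusive ranges.  A 20-s epoch gives 0.05 Hz spectral resolution, so
#' "the power of the i Hz component" is the periodogram power aggregated
#' over the 1-Hz bin centered on integer frequency i.
#'
#' @param epochs An `epoch_set` of raw (unfiltered) epochs; the sampling
#'   rate must be at least 200 Hz so the 100 Hz EMG band edge is below
#'   Nyquist.
#' @param window `"rectangular"` (matching the plain sums in the feature
#'   definitions) or `"hann"` taper before the periodogram.
#' @return A tibble with columns `epoch` (0-based), `p_eeg`, `p_emg`, `w`,
#'   `d`, `t`, `e`.
#' @export
extract_rf_features <- function(epochs, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  stopifnot(inherits(epochs, "epoch_set"))
  rate <- epochs$sampling_rate
  if (rate < 200) {
    abort(sprintf(
      "sampling rate %d Hz cannot resolve the 100 Hz EMG band edge (Nyquist)",
      rate))
  }
  L <- nrow(epochs$eeg)
  taper <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
  } else {
    rep(1, L)
  }
  pgram <- function(m) {
    X <- stats::mvfft(m * taper)
    (Mod(X)^2 / L)[seq_len(L %/% 2 + 1), , drop = FALSE]
  }
  freqs <- (seq_len(L %/% 2 + 1) - 1) * rate / L
  band_power <- function(P, lo, hi) {
    keep <- freqs >= (lo - 0.5) & freqs < (hi + 0.5)
    colSums(P[keep, , drop = FALSE])
  }
  Peeg <- pgram(epochs$eeg)
  Pemg <- pgram(epochs$emg)
  tibble(epoch = seq_len(n_epochs(epochs)) - 1L,
         p_eeg = colSums(abs(epochs$eeg)),
         p_emg = colSums(abs(epochs$emg)),
         w = band_power(Peeg, 1, 30),
         d = band_power(Peeg, 1, 6),
         t = band_power(Peeg, 7, 11),
         e = band_power(Pemg, 30, 100))
}

#' Random-forest baseline configuration
#'
#' The published comparison model: 20 trees, maximum depth 10, 2 candidate
#' features per split.
#'
#' @param n_trees,max_depth,max_features Forest hyperparameters.
#' @param seed Integer seed.
#' @return An `rf_config`.
#' @export
rf_config <- function(n_trees = 20, max_depth = 10, max_features = 2,
                      seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1, max_features >= 1)
  structure(list(n_trees = n_trees, max_depth = max_depth,
                 max_features = max_features, seed = seed),
            class = "rf_config")
}

RF_FEATURES <- c("p_eeg", "p_emg", "w", "d", "t", "e")

#' Train / apply the random-forest baseline scorer
#'
#' Fits a random forest on the six hand-crafted features (via the `ranger`
#' backend, which exposes tree count, depth and per-split feature count
#' directly).
#'
#' @param features Feature tibble from [extract_rf_features()].
#' @param labels Stage labels aligned with the feature rows.
#' @param config An [rf_config()].
#' @return `train_rf()` returns an `rf_sleep_scorer`; `predict_rf()` a
#'   factor of stage labels.
#' @export
train_rf <- function(features, labels, config = rf_config()) {
  y <- stage_factor(labels)
  if (length(y) != nrow(features)) {
    abort("labels must align with feature rows")
  }
  if (length(unique(y)) < 3) {
    abort(sprintf("stage(s) absent from training labels: %s",
                  paste(setdiff(STAGE_LEVELS, unique(as.character(y))),
                        collapse = ", ")))
  }
  dat <- as.data.frame(features[, RF_FEATURES])
  dat$stage <- y
  fit <- ranger::ranger(stage ~ ., data = dat,
                        num.trees = config$n_trees,
                        max.depth = config$max_depth,
                        mtry = config$max_features,
                        probability = FALSE, seed = config$seed,
                        num.threads = 1)
  structure(list(fit = fit, config = config, features = RF_FEATURES),
            class = "rf_sleep_scorer")
}

#' @rdname train_rf
#' @param classifier An `rf_sleep_scorer`.
#' @export
predict_rf <- function(classifier, features) {
  stopifnot(inherits(classifier, "rf_sleep_scorer"))
  missing <- setdiff(classifier$features, names(features))
  if (length(missing)) {
    abort(sprintf("feature column(s) missing: %s",
                  paste(missing, collapse = ", ")))
  }
  dat <- as.data.frame(features[, classifier$features])
  stage_factor(predict(classifier$fit, data = dat,
                       num.threads = 1)$predictions)
}
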