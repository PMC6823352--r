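# Shared fixtures, built in code.

# A desk-test network: 32 Hz, 1-s epochs, tiny branch geometry and heads,
# 5-epoch context.  Small enough for finite-difference gradient checks and
# fast training loops.
tiny_config <- function(variant = "full", dropout_rate = 0, context = 5,
                        normalize = FALSE) {
  sleep_model_config(
    sampling_rate = 32, epoch_length = 1, context = context, scale = 1,
    lstm_units = 8, fc_units = 6, ch1 = 2, ch2 = 3,
    dropout_rate = dropout_rate, variant = variant,
    narrow_geom = list(k1 = 8, s1 = 2, p1 = 2, k2 = 3, p2 = 2),
    wide_geom = list(k1 = 16, s1 = 4, p1 = 2, k2 = 3, p2 = 1),
    normalize = normalize)
}

# Synthetic dataset matched to tiny_config's geometry.  Short Markov
# hypnograms can miss the rare REM stage, so the seed advances until every
# stage is present (deterministic for a given starting seed).
tiny_dataset <- function(n_records = 2, epochs = 40, seed = 5,
                         config = tiny_config()) {
  repeat {
    man <- make_dataset(n_records, epochs, seed = seed,
                        sampling_rate = config$sampling_rate,
                        epoch_length = config$epoch_length)
    stages <- unlist(lapply(man$hypnogram, function(h) as.integer(h$stage)))
    if (length(unique(stages)) == 3) break
    seed <- seed + 1
  }
  list(manifest = man,
       dataset = labeled_dataset(man$record, man$hypnogram, config))
}

random_record <- function(n, rate = 250, seed = 1, id = "test") {
  set.seed(seed)
  signal_record(rnorm(n, sd = 50), rnorm(n, sd = 30), sampling_rate = rate,
                record_id = id)
}

# Independent per-epoch recount of all agreement metrics, straight from the
# formulas (loops, no shared code with compute_metrics()).
brute_metrics <- function(expert, predicted) {
  e <- as.integer(stages_of(expert))
  p <- as.integer(stages_of(predicted))
  stopifnot(length(e) == length(p))
  E <- matrix(0, 3, 3)
  for (i in seq_along(e)) E[e[i], p[i]] <- E[e[i], p[i]] + 1
  M <- length(e)
  rec <- prec <- numeric(3)
  for (s in 1:3) {
    rs <- sum(E[s, ]); cs <- sum(E[, s])
    rec[s] <- if (rs > 0) E[s, s] / rs else NA_real_
    prec[s] <- if (cs > 0) E[s, s] / cs else NA_real_
  }
  acc <- sum(diag(E)) / M
  pe <- 0
  for (s in 1:3) pe <- pe + (sum(E[s, ]) / M) * (sum(E[, s]) / M)
  list(confusion = E, recall = rec, precision = prec, accuracy = acc,
       p_e = pe, kappa = (acc - pe) / (1 - pe))
}

# Loop-based transcription of the moving-RMS definition (window of the Fs
# samples before t, reflect-padded first second).
brute_moving_rms <- function(x, fs, mode) {
  xp <- c(rev(x[seq_len(fs)]), x)
  vapply(seq_along(x), function(t) {
    ssq <- sum(xp[t:(t + fs - 1)]^2)
    if (mode == "paper") sqrt(ssq) / (fs - 1) else sqrt(ssq / fs)
  }, numeric(1))
}

model_features_for_test <- function(model, epochs) {
  sleepscorer:::model_features(model, epochs)
}

# The published Table 2 confusion matrix (expert rows, scorer columns).
table2_counts <- function() {
  matrix(c(14087311, 315295, 8187,
           233156, 12800870, 116645,
           39181, 243181, 1136074),
         nrow = 3, byrow = TRUE)
}
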