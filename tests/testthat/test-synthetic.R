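test_that("hypnogram sampling is seed-reproducible and obeys forbidden transitions", {
  tm <- transition_model()
  h1 <- sample_hypnogram(tm, 2000, seed = 3)
  h2 <- sample_hypnogram(tm, 2000, seed = 3)
  expect_identical(h1$stage, h2$stage)
  expect_false(identical(sample_hypnogram(tm, 2000, seed = 4)$stage, h1$stage))

  s <- as.integer(h1$stage)
  # P(WAKE -> REM) = 0 in the default matrix
  expect_equal(sum(s[-length(s)] == 1 & s[-1] == 3), 0)
})

test_that("invalid transition matrices are rejected", {
  bad <- matrix(c(0.9, 0.2, 0, 0.1, 0.8, 0.1, 0.2, 0.1, 0.7), 3, byrow = TRUE)
  expect_error(transition_model(bad), "sum to 1")
  neg <- matrix(c(1.1, -0.1, 0, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_error(transition_model(neg), "non-negative")
})

test_that("the default transition model's stationary law matches the stage prevalence", {
  tm <- transition_model()
  pi <- stationary_distribution(tm$transition_matrix)
  expect_equal(unname(pi), c(0.497, 0.454, 0.049), tolerance = 1e-9)
})

test_that("stage signatures produce the expected spectral and amplitude ordering", {
  params <- stage_signature_params()
  band_power <- function(x, rate, lo, hi) {
    L <- length(x)
    P <- Mod(stats::fft(x))^2 / L
    f <- (seq_len(L) - 1) * rate / L
    sum(P[f >= lo & f <= hi & f <= rate / 2])
  }
  h_nrem <- hypnogram(rep("N", 8), record_id = "nrem")
  r_nrem <- synthesize_record(h_nrem, params, sampling_rate = 250, seed = 21)
  es <- split_epochs(r_nrem, 20)
  delta <- apply(es$eeg, 2, band_power, rate = 250, lo = 1, hi = 4)
  theta <- apply(es$eeg, 2, band_power, rate = 250, lo = 6, hi = 9)
  expect_true(all(delta > theta))

  h_rem <- hypnogram(rep("R", 8), record_id = "rem")
  h_wake <- hypnogram(rep("W", 8), record_id = "wake")
  r_rem <- synthesize_record(h_rem, params, 250, seed = 22)
  r_wake <- synthesize_record(h_wake, params, 250, seed = 22)
  m_rem <- colMeans(abs(split_epochs(r_rem, 20)$emg))
  m_wake <- colMeans(abs(split_epochs(r_wake, 20)$emg))
  expect_true(all(m_rem < m_wake))
})

test_that("zero amplitude scales give all-zero signals", {
  params <- stage_signature_params(
    wake = list(bands = list(list(band = c(1, 30), weight = 1)),
                eeg_scale = 0, emg_scale = 0),
    nrem = list(bands = list(list(band = c(1, 4), weight = 1)),
                eeg_scale = 0, emg_scale = 0),
    rem = list(bands = list(list(band = c(6, 9), weight = 1)),
               eeg_scale = 0, emg_scale = 0))
  h <- hypnogram(c("W", "N", "R"))
  r <- synthesize_record(h, params, 100, seed = 1)
  expect_true(all(r$eeg == 0))
  expect_true(all(r$emg == 0))
})

test_that("signature parameter orderings are enforced", {
  expect_error(stage_signature_params(
    rem = list(bands = list(list(band = c(6, 9), weight = 1)),
               eeg_scale = 45, emg_scale = 70)),
    "WAKE > NREM > REM")
})

test_that("an all-zero noise spec leaves the record unchanged", {
  rec <- random_record(5000, 250, seed = 30)
  spec <- noise_spec(burst_amplitude = 0, mains_amplitude = 0, emg_mixing = 0)
  expect_identical(inject_noise(rec, spec, seed = 1), rec)
})

test_that("mains hum appears at its frequency with the closed-form sinusoid power", {
  rate <- 250; L <- rate * 20
  silent <- signal_record(rep(0, L), rep(0, L), rate)
  a <- 15
  noisy <- inject_noise(silent, noise_spec(burst_amplitude = 0,
                                           mains_frequency = 50,
                                           mains_amplitude = a,
                                           emg_mixing = 0), seed = 2)
  P <- Mod(stats::fft(noisy$eeg))^2 / L
  f <- (seq_len(L) - 1) * rate / L
  peak <- which.max(P[f <= rate / 2])
  expect_equal(f[peak], 50)
  # a sinusoid of amplitude a on an exact bin carries |X|^2/L = a^2 L / 4
  expect_equal(P[peak], a^2 * L / 4, tolerance = 1e-6)
})

test_that("burst count falls in the Poisson 99% interval of rate x duration", {
  rate <- 100
  hours <- 10
  rec <- signal_record(rep(0, rate * 3600 * hours), rep(0, rate * 3600 * hours),
                       rate)
  r_per_h <- 12
  noisy <- inject_noise(rec, noise_spec(burst_rate = r_per_h,
                                        mains_amplitude = 0, emg_mixing = 0),
                        seed = 5)
  n_bursts <- attr(noisy, "n_bursts")
  lam <- r_per_h * hours
  expect_gte(n_bursts, stats::qpois(0.005, lam))
  expect_lte(n_bursts, stats::qpois(0.995, lam))
})

test_that("emg contamination mixes the EMG into the EEG at the stated coefficient", {
  rec <- random_record(2000, 100, seed = 6)
  noisy <- inject_noise(rec, noise_spec(burst_amplitude = 0,
                                        mains_amplitude = 0,
                                        emg_mixing = 0.2), seed = 1)
  expect_equal(noisy$eeg, rec$eeg + 0.2 * rec$emg)
  expect_identical(noisy$emg, rec$emg)
})

test_that("make_dataset flags the rounded noisy count and reproduces bytewise", {
  m <- make_dataset(5, 4, noise_fraction = 0.4, seed = 77,
                    sampling_rate = 50, epoch_length = 2)
  expect_equal(sum(m$noisy), 2)
  m1 <- make_dataset(3, 5, seed = 12, sampling_rate = 50, epoch_length = 2)
  m2 <- make_dataset(3, 5, seed = 12, sampling_rate = 50, epoch_length = 2)
  expect_identical(m1$record, m2$record)
  expect_identical(m1$hypnogram, m2$hypnogram)
  # at least one record noisy whenever the fraction is positive
  m3 <- make_dataset(4, 3, noise_fraction = 0.05, seed = 1,
                     sampling_rate = 50, epoch_length = 2)
  expect_gte(sum(m3$noisy), 1)
  # epochs_per_record at 20 s gives the stated duration
  m4 <- make_dataset(1, 360, seed = 2, sampling_rate = 50)
  expect_equal(record_duration(m4$record[[1]]), 2 * 3600)
})

test_that("clean defaults are separable by a two-threshold classifier", {
  man <- make_dataset(4, 120, seed = 42)
  acc <- vapply(seq_len(nrow(man)), function(i) {
    es <- split_epochs(man$record[[i]], 20)
    labs <- as.integer(man$hypnogram[[i]]$stage)
    emg_amp <- colMeans(abs(es$emg))
    L <- nrow(es$eeg); rate <- es$sampling_rate
    f <- (seq_len(L) - 1) * rate / L
    P <- Mod(stats::mvfft(es$eeg))^2 / L
    delta <- colSums(P[f >= 1 & f <= 4, ])
    theta <- colSums(P[f >= 6 & f <= 9, ])
    # two thresholds: EMG splits WAKE from sleep, delta/theta splits the rest
    thr <- exp(mean(c(mean(log(emg_amp[labs == 1])),
                      mean(log(emg_amp[labs != 1])))))
    pred <- ifelse(emg_amp > thr, 1L, ifelse(delta > theta, 2L, 3L))
    mean(pred == labs)
  }, numeric(1))
  expect_gte(mean(acc), 0.85)
})
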