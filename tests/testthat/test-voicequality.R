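test_that("pitch tracker hits the generator F0 within 1 percent", {
  for (f0 in c(90, 150, 300)) {
    r <- synthesize_pulse_train(pulse_train_spec(f0, 1, seed = f0))
    tr <- track_pitch(r$audio)
    expect_gt(mean(tr$voiced), 0.5)
    expect_lt(abs(stats::median(tr$f0_hz[tr$voiced]) - f0) / f0, 0.01)
  }
})

test_that("silence has no voiced frames and empty period sequence", {
  set.seed(2)
  quiet <- audio_recording(stats::rnorm(16000, sd = 1e-6), 16000)
  tr <- track_pitch(quiet)
  expect_equal(sum(tr$voiced), 0)
  p <- extract_periods(quiet, tr)
  expect_equal(nrow(p), 0)
  expect_true(is.na(harmonics_to_noise(quiet, tr)))
})

test_that("a floor above the true F0 never yields voiced frames below it", {
  r <- synthesize_pulse_train(pulse_train_spec(150, 1))
  tr <- track_pitch(r$audio, floor_hz = 200)
  if (any(tr$voiced)) expect_true(all(tr$f0_hz[tr$voiced] >= 200))
  else succeed()
})

test_that("extracted periods of an unperturbed train are constant to one sample", {
  r <- synthesize_pulse_train(pulse_train_spec(100, 1))
  tr <- track_pitch(r$audio)
  p <- extract_periods(r$audio, tr)
  per <- unlist(lapply(split(p$epoch_s, p$run), diff))
  expect_gt(length(per), 50)
  expect_true(all(abs(per - 0.010) <= 1 / 16000))
})

test_that("extracted period dispersion tracks the ground truth under jitter", {
  r <- synthesize_pulse_train(pulse_train_spec(100, 2, jitter_rel = 0.02, seed = 8))
  gt_cv <- stats::sd(r$ground_truth$periods_s) / mean(r$ground_truth$periods_s)
  tr <- track_pitch(r$audio)
  p <- extract_periods(r$audio, tr)
  per <- unlist(lapply(split(p$epoch_s, p$run), diff))
  cv <- stats::sd(per) / mean(per)
  expect_lt(abs(cv - gt_cv) / gt_cv, 0.20)
})

test_that("jitter formulas match hand evaluation and identities hold", {
  p <- period_sequence(cumsum(c(0, 10, 11, 10, 11)) / 1000,
                       rep(1, 5))
  jm <- jitter_measures(p)
  expect_equal(jm$jitter_local, 1 / 10.5)
  expect_equal(jm$jitter_local_abs_s, 0.001)
  expect_equal(jm$jitter_ddp, 3 * jm$jitter_rap)
  const <- jitter_measures(period_sequence(seq(0, 0.05, by = 0.01), rep(1, 6)))
  expect_equal(const$jitter_local, 0)
  expect_equal(const$jitter_rap, 0)
  expect_equal(const$jitter_ppq5, 0)
})

test_that("shimmer formulas match hand evaluation and identities hold", {
  p <- period_sequence(seq(0, 0.03, by = 0.01), c(1.0, 1.1, 1.0, 1.1))
  sm <- shimmer_measures(p)
  expect_equal(sm$shimmer_local, 0.1 / 1.05)
  expect_equal(sm$shimmer_local_db, 20 * log10(1.1), tolerance = 1e-12)
  expect_equal(sm$shimmer_dda, 3 * sm$shimmer_apq3)
  const <- shimmer_measures(period_sequence(seq(0, 0.1, by = 0.01), rep(0.5, 11)))
  expect_equal(const$shimmer_local, 0)
  expect_equal(const$shimmer_apq11, 0)
})

test_that("too few cycles gives missing perturbation fields with a reason", {
  p <- period_sequence(c(0, 0.01), c(1, 1))
  jm <- jitter_measures(p)
  expect_true(is.na(jm$jitter_local))
  expect_match(attr(jm, "reason"), "fewer than 3")
})

test_that("clean trains show high HNR and noisy trains match the SNR", {
  r <- synthesize_pulse_train(pulse_train_spec(150, 1, seed = 4))
  tr <- track_pitch(r$audio)
  expect_gt(harmonics_to_noise(r$audio, tr), 25)
  rn <- synthesize_pulse_train(pulse_train_spec(150, 2, snr_db = 10, seed = 6))
  trn <- track_pitch(rn$audio)
  expect_lt(abs(harmonics_to_noise(rn$audio, trn) - 10), 2)
})

test_that("F0 statistics use the population SD convention", {
  tr <- speechmarkers:::new_pitch_track(
    tibble::tibble(frame_time_s = c(0.01, 0.02), f0_hz = c(100, 140),
                   voiced = c(TRUE, TRUE), strength = c(0.9, 0.9)), 75, 500)
  fs <- f0_statistics(tr)
  expect_equal(fs$f0_mean_hz, 120)
  expect_equal(fs$f0_sd_hz, 20)
  tr0 <- speechmarkers:::new_pitch_track(
    tibble::tibble(frame_time_s = 0.01, f0_hz = 0, voiced = FALSE,
                   strength = 0.2), 75, 500)
  expect_true(is.na(f0_statistics(tr0)$f0_mean_hz))
})

test_that("voice-quality outputs are invariant to amplitude scaling", {
  r <- synthesize_pulse_train(pulse_train_spec(120, 1, jitter_rel = 0.01,
                                               shimmer_rel = 0.02, seed = 13))
  a1 <- r$audio
  a2 <- audio_recording(a1$samples * 0.35, a1$sample_rate_hz)
  f1 <- acoustic_features(a1)
  f2 <- acoustic_features(a2)
  for (col in names(f1)) {
    expect_equal(f1[[col]], f2[[col]], tolerance = 1e-6, label = col)
  }
})

test_that("prepending silence leaves voice-quality outputs nearly unchanged", {
  r <- synthesize_pulse_train(pulse_train_spec(140, 1, jitter_rel = 0.01, seed = 17))
  a1 <- r$audio
  set.seed(3)
  pad <- stats::rnorm(round(0.3 * a1$sample_rate_hz), sd = 1e-6)
  a2 <- audio_recording(c(pad, a1$samples), a1$sample_rate_hz)
  f1 <- acoustic_features(a1)
  f2 <- acoustic_features(a2)
  expect_equal(f1$f0_mean_hz, f2$f0_mean_hz, tolerance = 0.01)
  expect_equal(f1$jitter_local, f2$jitter_local, tolerance = 0.15)
  expect_equal(f1$hnr_mean_db, f2$hnr_mean_db, tolerance = 2)
})

test_that("mean extracted jitter and shimmer recover the analytic expectation", {
  sigma <- 0.01
  expected <- 2 * sigma / sqrt(pi)
  jl <- sl <- numeric(8)
  for (k in seq_len(8)) {
    r <- synthesize_pulse_train(pulse_train_spec(100 + 10 * k, 2,
                                                 jitter_rel = sigma,
                                                 shimmer_rel = sigma,
                                                 seed = 300 + k))
    tr <- track_pitch(r$audio)
    p <- extract_periods(r$audio, tr)
    jl[k] <- jitter_measures(p)$jitter_local
    sl[k] <- shimmer_measures(p)$shimmer_local
  }
  expect_lt(abs(mean(jl) - expected) / expected, 0.25)
  expect_lt(abs(mean(sl) - expected) / expected, 0.25)
})
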