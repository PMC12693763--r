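test_that("flat-line detection flags silent and slow signals", {
  cfg <- preprocess_config()
  expect_true(detect_flat_line(ecg_signal(rep(0, 1000), 200), cfg))
  expect_true(detect_flat_line(ecg_signal(rep(1, 1000), 200), cfg))
  g <- clean_5s(seed = 1, hr = 60)
  expect_false(detect_flat_line(g$signal,
                                preprocess_config(min_peaks = 3L)))
})

test_that("median-filter cascade removes baseline wander", {
  cfg <- preprocess_config()
  const <- remove_baseline(ecg_signal(rep(0.7, 2000), 200), cfg)
  expect_lt(max(abs(const$samples)), 1e-12)

  g <- clean_10s(seed = 2)
  tt <- (seq_along(g$signal$samples) - 1) / 200
  drift <- 0.5 * sin(2 * pi * 0.3 * tt)
  drifted <- ecg_signal(g$signal$samples + drift, 200)
  out <- remove_baseline(drifted, cfg)
  p_in <- ecgmtl:::band_power_fraction(drifted$samples, 200, 0, 1) *
    sum((drifted$samples - mean(drifted$samples))^2)
  p_out <- ecgmtl:::band_power_fraction(out$samples, 200, 0, 1) *
    sum((out$samples - mean(out$samples))^2)
  expect_lt(p_out, 0.1 * p_in)

  # near-no-op on an already baseline-free ECG
  out2 <- remove_baseline(g$signal, cfg)
  expect_gte(stats::cor(out2$samples, g$signal$samples), 0.98)

  expect_error(remove_baseline(ecg_signal(rnorm(50), 200), cfg), "shorter")
})

test_that("band-pass keeps the ECG band and zeroes the isoline", {
  cfg <- preprocess_config()
  tt <- (0:1999) / 200
  s60 <- ecg_signal(sin(2 * pi * 60 * tt), 200)
  out60 <- bandpass_smooth(s60, cfg)
  expect_lt(sqrt(mean(out60$samples^2)), 0.05 * sqrt(mean(s60$samples^2)))

  s10 <- ecg_signal(sin(2 * pi * 10 * tt), 200)
  out10 <- bandpass_smooth(s10, cfg)
  expect_gte(sqrt(mean(out10$samples^2)), 0.8 * sqrt(mean(s10$samples^2)))
  expect_lt(abs(mean(out10$samples)), 1e-9)

  expect_error(bandpass_smooth(ecg_signal(rnorm(400), 60),
                               preprocess_config(target_fs = 200)),
               "Nyquist")
})

test_that("resampling changes length consistently and preserves content", {
  x <- ecg_signal(rnorm(1000), 200)
  expect_identical(resample_to(x, 200), x)

  tt <- (0:4999) / 1000
  x1k <- ecg_signal(sin(2 * pi * 5 * tt), 1000)
  y <- resample_to(x1k, 200)
  expect_length(y$samples, 1000L)
  expect_equal(y$fs, 200)

  tt4 <- (0:1999) / 400
  x400 <- ecg_signal(sin(2 * pi * 5 * tt4), 400)
  y200 <- resample_to(x400, 200)
  ref <- sin(2 * pi * 5 * (seq_along(y200$samples) - 1) / 200)
  expect_gte(stats::cor(y200$samples, ref), 0.999)
})

test_that("Pan-Tompkins recovers annotated R peaks on clean and noisy ECG", {
  g <- clean_10s(seed = 3)
  det <- detect_rpeaks(g$signal)
  m <- match_peaks(g$annotations$r_peaks, det$r_peaks, tol = 10L)
  expect_gte(length(det$r_peaks), 9L)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)

  expect_length(detect_rpeaks(ecg_signal(rep(0, 1000), 200))$r_peaks, 0L)

  # medium-level muscle artifact at 6 dB
  ma <- generate_noise("MA", 10, 200, seed = 4)
  nz <- scale_noise_to_snr(g$signal, ma, 6)
  noisy <- ecg_signal(g$signal$samples + nz$samples, 200)
  detn <- detect_rpeaks(noisy)
  mn <- match_peaks(g$annotations$r_peaks, detn$r_peaks, tol = 10L)
  expect_gte(mn$recall, 0.90)

  expect_error(detect_rpeaks(ecg_signal(rnorm(100), 200)), "2 s")
})

test_that("R-peak detection meets 95% recall/precision over many records", {
  rec <- prec <- numeric(40)
  for (i in seq_len(40)) {
    g <- generate_clean_ecg(10, 200, 55 + (i %% 40), seed = 1000 + i)
    det <- detect_rpeaks(g$signal)
    m <- match_peaks(g$annotations$r_peaks, det$r_peaks, tol = 10L)
    rec[i] <- m$recall; prec[i] <- m$precision
  }
  expect_gte(mean(rec), 0.95)
  expect_gte(mean(prec), 0.95)
})

test_that("full preprocessing chain is near-idempotent on clean ECG", {
  g <- clean_10s(seed = 5)
  cfg <- preprocess_config(min_peaks = 3L)
  once <- preprocess_ecg(g$signal, cfg)
  twice <- preprocess_ecg(once$signal, cfg)
  expect_gte(stats::cor(once$signal$samples, twice$signal$samples), 0.99)
  expect_false(once$flat_line)
})
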