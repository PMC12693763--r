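# Reference-clean segments for selector tests are Good-category mixtures
# (minor EM/MA noise at >= 16 dB plus small baseline wander): the clean
# reference recordings this selector emulates tolerate minor artifacts, and
# probes must come from the same generative family.
sqi_segment <- function(seed, category = "GOOD", snr_override = NULL) {
  g <- generate_clean_ecg(10, 200, 55 + (seed %% 40), seed = 300 + seed)
  ma <- generate_noise("MA", 20, 200, seed = 500 + seed)
  if (is.null(snr_override)) {
    em <- generate_noise("EM", 20, 200, seed = 400 + seed)
    s <- synthesize_noisy_sample(g$signal, g$annotations, category,
                                 mixing_policy(), em = em, ma = ma,
                                 seed = 600 + seed, pure_noise_prob = 0)
    s$noisy
  } else {
    nz <- scale_noise_to_snr(g$signal,
                             ecg_signal(ma$samples[1:2000], 200),
                             snr_override)
    bw <- generate_noise("BW", 10, 200, seed = 450 + seed)
    ecg_signal(g$signal$samples + nz$samples + 0.1 * bw$samples, 200)
  }
}

sqi_reference_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- t(vapply(1:40, function(i)
        compute_sqi_features(sqi_segment(i)), numeric(11)))
    cache
  }
})

test_that("SQI features match closed-form values on reference signals", {
  tt <- (0:999) / 200
  sine <- ecg_signal(sin(2 * pi * 10 * tt), 200)
  f <- compute_sqi_features(sine)
  expect_gte(f[["f6"]], 0.99)

  set.seed(1)
  wn <- ecg_signal(rnorm(12000), 200)
  fw <- compute_sqi_features(wn)
  expect_lt(abs(fw[["f1"]] - 3), 0.3)  # Pearson kurtosis of Gaussian noise

  # identical template beats on a rigid RR grid: zero RR-difference spread
  rigid <- generate_clean_ecg(10, 200, 60,
                              morphology = ecg_morphology(rr_jitter_sd = 0),
                              seed = 3)
  fr <- compute_sqi_features(rigid$signal, rigid$annotations)
  expect_equal(fr[["f9"]], 0, tolerance = 1e-12)

  expect_error(compute_sqi_features(ecg_signal(1, 200)), "too short")
})

test_that("proportions and band ratios stay in [0, 1]; scale invariance", {
  set.seed(4)
  scale_inv <- c("f1", "f3", "f4", "f5", "f6", "f7")
  for (i in 1:5) {
    x <- rnorm(1000) + 0.3 * sin(2 * pi * 7 * (0:999) / 200)
    f1v <- compute_sqi_features(ecg_signal(x, 200))
    f2v <- compute_sqi_features(ecg_signal(3.7 * x, 200))
    expect_equal(f1v[scale_inv], f2v[scale_inv], tolerance = 1e-9)
    expect_true(all(f1v[c("f3", "f4", "f5", "f6", "f7")] >= 0))
    expect_true(all(f1v[c("f3", "f4", "f5", "f6", "f7")] <= 1))
  }
})

test_that("one-class selector accepts clean training data, rejects outliers", {
  feats <- sqi_reference_features()
  sel <- fit_clean_selector(feats, nu = 0.1)
  expect_gte(mean(predict_clean(sel, feats)), 0.85)

  far <- matrix(rep(sel$center + 10 * sel$scale, 2), 2, byrow = TRUE)
  expect_false(any(predict_clean(sel, far)))

  expect_error(fit_clean_selector(feats[0, , drop = FALSE]), "empty")
  expect_error(fit_clean_selector(feats[1:5, , drop = FALSE]), "at least 20")
})

test_that("selector separates Good from heavily corrupted segments", {
  sel <- fit_clean_selector(sqi_reference_features())
  good <- lapply(61:80, function(i) sqi_segment(i, "GOOD"))
  bad <- lapply(61:80, function(i) sqi_segment(i, "BAD"))
  segs <- c(good, bad)
  idx <- select_clean_segments(segs, sel)
  expect_identical(idx, select_clean_segments(segs, sel))  # deterministic
  expect_gt(length(idx), 0L)
  expect_gte(mean(idx <= 20), 0.80)  # accepted mostly from the Good set
  expect_identical(select_clean_segments(list(), sel), integer(0))
  expect_error(select_clean_segments(segs, "nope"), "not a fitted")
})

test_that("acceptance rate degrades monotonically as mixing SNR drops", {
  sel <- fit_clean_selector(sqi_reference_features())
  rates <- vapply(c(18, 10, 0, -4), function(snr) {
    mean(vapply(41:58, function(i)
      predict_clean(sel, t(compute_sqi_features(
        sqi_segment(i, snr_override = snr)))), TRUE))
  }, 0)
  expect_true(all(diff(rates) <= 0.05 + 1e-9))  # non-increasing (small slack)
  expect_gt(rates[1], rates[4])
})
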