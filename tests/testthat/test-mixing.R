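test_that("scale_noise_to_snr hits any target exactly", {
  cl <- clean_5s(seed = 1)$signal
  nz <- generate_noise("MA", 5, 200, seed = 2)
  for (target in c(-20, -5, 0, 10, 18, 40)) {
    sc <- scale_noise_to_snr(cl, nz, target)
    expect_lt(abs(realized_snr(cl$samples, cl$samples + sc$samples) - target),
              1e-9)
  }
  # equal-power noise at 0 dB keeps scale 1
  nz0 <- ecg_signal(nz$samples * sqrt(sum(cl$samples^2) / sum(nz$samples^2)),
                    200)
  sc0 <- scale_noise_to_snr(cl, nz0, 0)
  expect_equal(sc0$samples, nz0$samples, tolerance = 1e-12)
  expect_error(scale_noise_to_snr(cl, ecg_signal(rep(0, 1000), 200), 10),
               "zero power")
})

test_that("synthesized samples stay in their category's SNR range", {
  pol <- mixing_policy()
  cl <- clean_5s(seed = 3)
  em <- generate_noise("EM", 12, 200, seed = 4)
  ma <- generate_noise("MA", 12, 200, seed = 5)
  ranges <- list(GOOD = c(16, 18), MEDIUM = c(5, 14), BAD = c(-5, -3))
  for (cat in names(ranges)) {
    for (sd_ in 1:10) {
      s <- synthesize_noisy_sample(cl$signal, cl$annotations, cat, pol,
                                   em = em, ma = ma, seed = sd_,
                                   pure_noise_prob = 0)
      expect_gte(s$snr_db, ranges[[cat]][1] - 1e-9)
      expect_lte(s$snr_db, ranges[[cat]][2] + 1e-9)
      expect_equal(s$category, ecgmtl::QUALITY_LEVELS[[cat]][[1]])
    }
  }
})

test_that("noisy minus clean equals the injected noise exactly", {
  pol <- mixing_policy(include_bw = FALSE)
  cl <- clean_5s(seed = 6)
  em <- generate_noise("EM", 12, 200, seed = 7)
  ma <- generate_noise("MA", 12, 200, seed = 8)
  s <- synthesize_noisy_sample(cl$signal, cl$annotations, "MEDIUM", pol,
                               em = em, ma = ma, seed = 9,
                               pure_noise_prob = 0)
  resid <- s$noisy$samples - s$clean$samples
  expect_lt(abs(realized_snr(s$clean$samples, s$clean$samples + resid) -
                  s$snr_db), 1e-9)
})

test_that("weak R-R labels follow the SNR/correlation rule per segment", {
  cl <- clean_10s(seed = 10)
  n <- length(cl$signal$samples)
  base <- structure(list(clean = cl$signal, noisy = cl$signal,
                         category = 1L, r_peaks = cl$annotations$r_peaks),
                    class = "noisy_sample")
  expect_equal(compute_rr_noise_labels(base), rep(0, n))

  # corrupt exactly one R-R interval
  r <- cl$annotations$r_peaks
  i0 <- r[4] + 1L; i1 <- r[5]
  noisy <- cl$signal$samples
  set.seed(11)
  noisy[i0:i1] <- noisy[i0:i1] + rnorm(i1 - i0 + 1L, sd = 1.0)
  s1 <- base; s1$noisy <- ecg_signal(noisy, 200)
  lab <- compute_rr_noise_labels(s1, snr_thr = 5, corr_thr = 0.8)
  expect_true(all(lab[i0:i1] == 1))
  expect_true(all(lab[-(i0:i1)] == 0))

  # every interval corrupted
  all_noisy <- cl$signal$samples + rnorm(n, sd = 2)
  s2 <- base; s2$noisy <- ecg_signal(all_noisy, 200)
  expect_equal(compute_rr_noise_labels(s2), rep(1, n))

  # fewer than 2 peaks: global labeling with a warning
  s3 <- base; s3$r_peaks <- integer(0)
  expect_warning(lab3 <- compute_rr_noise_labels(s3), "fewer than 2")
  expect_equal(lab3, rep(0, n))
})

test_that("lowering SNR never decreases labeled-noisy segments", {
  pol <- mixing_policy(include_bw = FALSE,
                       blend_choices = list(c(0.5, 0.5)))
  cl <- clean_10s(seed = 12)
  ma <- generate_noise("MA", 20, 200, seed = 13)
  em <- generate_noise("EM", 20, 200, seed = 14)
  n_flagged <- vapply(c(20, 10, 5, 0, -5), function(snr) {
    nz <- scale_noise_to_snr(cl$signal,
                             ecg_signal(0.7 * ma$samples[1:2000] +
                                          0.3 * em$samples[1:2000], 200), snr)
    s <- structure(list(clean = cl$signal,
                        noisy = ecg_signal(cl$signal$samples + nz$samples, 200),
                        r_peaks = cl$annotations$r_peaks),
                   class = "noisy_sample")
    sum(compute_rr_noise_labels(s))
  }, 0)
  expect_true(all(diff(n_flagged) >= 0))
})

test_that("pure-noise Bad windows carry all-one labels and no beats", {
  pol <- mixing_policy()
  cl <- clean_5s(seed = 15)
  em <- generate_noise("EM", 12, 200, seed = 16)
  ma <- generate_noise("MA", 12, 200, seed = 17)
  s <- synthesize_noisy_sample(cl$signal, cl$annotations, "BAD", pol,
                               em = em, ma = ma, seed = 18,
                               pure_noise_prob = 1)
  expect_true(s$pure_noise)
  expect_equal(s$noise_level, rep(1, 1000))
  expect_length(s$r_peaks, 0L)
})
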