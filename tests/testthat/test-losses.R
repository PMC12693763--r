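test_that("wavelet importance mask is binary and covers the QRS complexes", {
  expect_equal(wavelet_importance_mask(rep(0, 1000)), rep(0, 1000))

  g <- clean_5s(seed = 1, hr = 72)
  mask <- wavelet_importance_mask(g$signal$samples)
  expect_true(all(mask %in% c(0, 1)))
  expect_length(mask, 1000L)

  fid <- g$annotations$fiducials
  cov <- numeric(0)
  for (b in seq_len(nrow(fid))) {
    if (is.na(fid$qrs_onset[b]) || is.na(fid$qrs_offset[b])) next
    lo <- max(1L, fid$qrs_onset[b] + 1L - 4L)   # 20 ms margin at 200 Hz
    hi <- min(1000L, fid$qrs_offset[b] + 1L + 4L)
    cov <- c(cov, mask[lo:hi])
  }
  expect_gte(mean(cov), 0.90)

  # matrix input keeps shape
  M <- wavelet_importance_mask(rbind(g$signal$samples, g$signal$samples))
  expect_identical(dim(M), c(2L, 1000L))
})

test_that("denoising loss follows the masked, category-weighted form", {
  B <- 3L; Tn <- 100L
  tgt <- matrix(0, B, Tn)
  mask1 <- matrix(1, B, Tn)

  # perfect reconstruction
  expect_equal(denoising_loss(tgt, tgt, y = c(1, 2, 3), mask = mask1), 0)

  # all-Bad batch contributes nothing
  pred <- matrix(rnorm(B * Tn), B)
  expect_equal(denoising_loss(pred, tgt, y = rep(3L, B), mask = mask1), 0)

  # single Good sample, constant error e, all-ones mask, alpha 2 -> 2 e^2
  e <- 0.31
  pred1 <- matrix(e, 1L, Tn)
  expect_equal(denoising_loss(pred1, matrix(0, 1L, Tn), y = 1L,
                              mask = matrix(1, 1L, Tn), alpha = 2),
               2 * e^2, tolerance = 1e-12)

  # alpha = 1 reduces to plain masked MSE over non-Bad samples (oracle)
  set.seed(2)
  pred <- matrix(rnorm(B * Tn), B)
  msk <- matrix(rbinom(B * Tn, 1, 0.3), B)
  y <- c(1L, 2L, 3L)
  got <- denoising_loss(pred, tgt, y, mask = msk, alpha = 1)
  oracle <- mean(c(mean(pred[1, ]^2), mean(pred[2, ]^2)))
  expect_equal(got, oracle, tolerance = 1e-12)

  # Bad samples' content cannot move the loss
  pred_b <- pred; pred_b[3, ] <- pred_b[3, ] + 100
  expect_equal(denoising_loss(pred_b, tgt, y, mask = msk, alpha = 2),
               denoising_loss(pred, tgt, y, mask = msk, alpha = 2))

  expect_error(denoising_loss(pred, tgt, y, mask = msk, alpha = 0.5),
               "alpha")
})

test_that("denoising loss gradient matches finite differences", {
  set.seed(3)
  B <- 2L; Tn <- 40L
  tgt <- matrix(rnorm(B * Tn), B)
  pred <- matrix(rnorm(B * Tn), B)
  msk <- matrix(rbinom(B * Tn, 1, 0.5), B)
  y <- c(1L, 2L)
  r <- denoising_loss(pred, tgt, y, mask = msk, alpha = 2, grad = TRUE)
  eps <- 1e-6
  for (k in 1:10) {
    i <- sample(B, 1); j <- sample(Tn, 1)
    pp <- pred; pp[i, j] <- pp[i, j] + eps
    pm <- pred; pm[i, j] <- pm[i, j] - eps
    num <- (denoising_loss(pp, tgt, y, mask = msk, alpha = 2) -
              denoising_loss(pm, tgt, y, mask = msk, alpha = 2)) / (2 * eps)
    expect_equal(r$grad[i, j], num, tolerance = 1e-6)
  }
})

test_that("cross-entropy has its closed forms and clamps zero probabilities", {
  onehot <- matrix(c(1, 0, 0), 1L)
  expect_equal(classification_loss(1L, onehot), 0)

  unif <- matrix(1 / 3, 4L, 3L)
  expect_equal(classification_loss(c(1L, 2L, 3L, 1L), unif), log(3),
               tolerance = 1e-12)

  set.seed(4)
  logits <- matrix(rnorm(15), 5L)
  p <- exp(logits) / rowSums(exp(logits))
  y <- sample(1:3, 5L, replace = TRUE)
  expect_equal(classification_loss(y, p),
               -sum(log(p[cbind(1:5, y)])) / 5, tolerance = 1e-9)

  zero <- matrix(c(0, 1, 0), 1L)
  expect_true(is.finite(classification_loss(1L, zero)))
})

test_that("noise-level MSE equals the naive double-loop oracle", {
  expect_equal(noise_level_loss(matrix(0.5, 2, 10), matrix(0.5, 2, 10)), 0)
  expect_equal(noise_level_loss(matrix(0, 2, 10), matrix(1, 2, 10)), 1)
  set.seed(5)
  a <- matrix(runif(60), 3); b <- matrix(runif(60), 3)
  oracle <- 0
  for (i in 1:3) for (j in 1:20) oracle <- oracle + (a[i, j] - b[i, j])^2
  expect_equal(noise_level_loss(a, b), oracle / 60, tolerance = 1e-12)
  expect_error(noise_level_loss(a, b[, 1:10]), "mismatch")
})

test_that("uncertainty weighting obeys its calculus", {
  L <- c(0.8, 1.3, 0.2)
  expect_equal(total_loss(L, c(0, 0, 0)), sum(L) / 2, tolerance = 1e-12)

  # increasing sigma decreases the weighted task term
  term <- function(ls) L[1] / (2 * exp(2 * ls))
  expect_lt(term(0.5), term(0))

  # d/d log sigma = 1 - L / sigma^2, checked by finite differences
  ls <- c(0.2, -0.3, 0.1)
  r <- total_loss(L, ls, grad = TRUE)
  eps <- 1e-7
  for (i in 1:3) {
    lp <- ls; lp[i] <- lp[i] + eps
    lm <- ls; lm[i] <- lm[i] - eps
    num <- (total_loss(L, lp) - total_loss(L, lm)) / (2 * eps)
    expect_equal(r$d_log_sigma[i], num, tolerance = 1e-5)
    expect_equal(r$d_log_sigma[i], 1 - L[i] / exp(2 * ls[i]),
                 tolerance = 1e-12)
  }

  # stationary point of L/(2 s^2) + log s at s^2 = L: gradient changes sign
  s_star <- sqrt(L[1])
  g_lo <- 1 - L[1] / (0.9 * s_star)^2
  g_hi <- 1 - L[1] / (1.1 * s_star)^2
  expect_lt(g_lo, 0)
  expect_gt(g_hi, 0)

  # may be negative via log sigma, but always finite
  expect_true(is.finite(total_loss(c(1e-6, 1e-6, 1e-6), c(-3, -3, -3))))
})
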