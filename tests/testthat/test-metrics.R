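test_that("classification metrics match hand-computed confusion algebra", {
  y <- c(1, 1, 2, 2, 3, 3)
  expect_equal(classification_metrics(y, y)$accuracy, 1)
  perfect <- classification_metrics(y, y)
  expect_true(all(perfect$per_class$precision == 1))
  expect_true(all(perfect$per_class$f1 == 1))

  # one class with TP = 8, FP = 2, FN = 2
  y_true <- c(rep(1, 10), rep(2, 10))
  y_pred <- c(rep(1, 8), 2, 2, 1, 1, rep(2, 8))
  m <- classification_metrics(y_true, y_pred)
  expect_equal(m$per_class["Good", "precision"], 0.8)
  expect_equal(m$per_class["Good", "recall"], 0.8)
  expect_equal(m$per_class["Good", "f1"], 0.8)

  # toy 3-class confusion [[5,1,0],[1,4,0],[0,0,9]]
  yt <- c(rep(1, 6), rep(2, 5), rep(3, 9))
  yp <- c(rep(1, 5), 2, 1, rep(2, 4), rep(3, 9))
  m3 <- classification_metrics(yt, yp)
  expect_identical(as.vector(m3$confusion),
                   as.integer(matrix(c(5, 1, 0, 1, 4, 0, 0, 0, 9), 3,
                                     byrow = TRUE)))
  p1 <- 5 / 6; r1 <- 5 / 6; f1 <- 2 * p1 * r1 / (p1 + r1)
  p2 <- 4 / 5; r2 <- 4 / 5; f2 <- 2 * p2 * r2 / (p2 + r2)
  wf1 <- (6 * f1 + 5 * f2 + 9 * 1) / 20
  expect_equal(m3$weighted[["f1"]], wf1, tolerance = 1e-9)

  # marginals reconcile and weighted F1 lies between per-class extremes
  expect_equal(sum(m3$confusion), 20)
  expect_gte(m3$weighted[["f1"]], min(m3$per_class$f1))
  expect_lte(m3$weighted[["f1"]], max(m3$per_class$f1))

  expect_error(classification_metrics(integer(0), integer(0)), "empty")
})

test_that("denoising metrics satisfy their algebraic identities", {
  set.seed(1)
  x <- rnorm(500)

  m_id <- denoising_metrics(x, x)
  expect_equal(m_id$prd, 0)
  expect_equal(m_id$rmse, 0)
  expect_equal(m_id$cossim, 1, tolerance = 1e-12)
  expect_true(m_id$exact)
  expect_identical(m_id$snr_db, Inf)

  # doubling: residual energy equals signal energy -> PRD 100, CosSim 1
  m2 <- denoising_metrics(x, 2 * x)
  expect_equal(m2$prd, 100, tolerance = 1e-9)
  expect_equal(m2$cossim, 1, tolerance = 1e-12)
  expect_equal(m2$snr_db, 0, tolerance = 1e-9)

  # constant offset: RMSE = |c|
  m_off <- denoising_metrics(x, x + 0.37)
  expect_equal(m_off$rmse, 0.37, tolerance = 1e-12)

  # CosSim is scale invariant
  y <- rnorm(500)
  expect_equal(denoising_metrics(x, y)$cossim,
               denoising_metrics(x, 5 * y)$cossim, tolerance = 1e-12)

  # naive summation oracle
  xh <- x + rnorm(500, sd = 0.2)
  m <- denoising_metrics(x, xh)
  expect_equal(m$prd, 100 * sqrt(sum((x - xh)^2) / sum(x^2)),
               tolerance = 1e-10)
  expect_equal(m$snr_db, 10 * log10(sum(x^2) / sum((x - xh)^2)),
               tolerance = 1e-10)
  expect_equal(m$cossim, sum(x * xh) / sqrt(sum(x^2) * sum(xh^2)),
               tolerance = 1e-10)
})

test_that("batch sampler respects category mix, SNR ranges and determinism", {
  pool <- default_pool()
  b1 <- make_batch(pool, 64L, step_seed = 5L)
  expect_identical(dim(b1$x), c(64L, 1000L))
  expect_true(all(b1$y %in% 1:3))
  tab <- tabulate(b1$y, 3L)
  expect_true(all(tab >= 8L))  # multinomial bounds for p = 1/3, n = 64

  b2 <- make_batch(pool, 64L, step_seed = 5L)
  expect_identical(b1$x, b2$x)
  expect_identical(b1$y, b2$y)

  ranges <- list(c(16, 18), c(5, 14), c(-5, -3))
  for (i in seq_len(64L)) {
    s <- b1$samples[[i]]
    if (isTRUE(s$pure_noise)) next
    r <- ranges[[s$category]]
    snr <- realized_snr(s$clean$samples,
                        s$clean$samples + (s$noisy$samples - s$clean$samples))
    expect_gte(s$snr_db, r[1] - 1e-9)
    expect_lte(s$snr_db, r[2] + 1e-9)
  }
})

test_that("an untrained model classifies a balanced corpus at chance level", {
  pool <- default_pool()
  m <- build_model(model_config(enc_blocks = 1L, dec_blocks = 1L), seed = 3L)
  tb <- make_batch(pool, 90L, step_seed = 11L)
  rep <- evaluate_model(m, tb$samples)
  # binomial 99% band around 1/3 for n = 90
  expect_gte(rep$classification$accuracy, 1 / 3 - 2.58 * sqrt(2 / 9 / 90))
  expect_lte(rep$classification$accuracy, 1 / 3 + 2.58 * sqrt(2 / 9 / 90))
  expect_identical(nrow(rep$by_bin), 3L)
})
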