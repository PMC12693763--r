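#' Training configuration
#'
#' Defaults mirror the published training recipe: Adam with learning rate
#' 1e-3 and weight decay 0.05, Xavier initialization, 50 epochs at batch
#' size 64, denoising amplification `alpha = 2`, balanced category sampling.
#' `steps_per_epoch` bounds the number of online-augmented batches per
#' epoch (fresh noise realizations are drawn every step, so an epoch is a
#' step budget rather than a sweep over a fixed corpus).
#'
#' @param epochs Number of epochs.
#' @param batch_size Samples per batch.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty added to weight gradients.
#' @param alpha Denoising-loss amplification factor.
#' @param category_mix Sampling proportions over (Good, Medium, Bad);
#'   must sum to 1.
#' @param steps_per_epoch Batches per epoch.
#' @param val_size Held-out synthetic validation samples (0 disables).
#' @param seed Base seed for all randomness in the run.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 50L, batch_size = 64L, lr = 1e-3,
                         weight_decay = 0.05, alpha = 2,
                         category_mix = c(1, 1, 1) / 3,
                         steps_per_epoch = 10L, val_size = 0L, seed = 1L) {
  stopifnot(abs(sum(category_mix) - 1) < 1e-9, all(category_mix >= 0),
            epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, alpha = alpha,
                 category_mix = category_mix,
                 steps_per_epoch = as.integer(steps_per_epoch),
                 val_size = as.integer(val_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Build a reusable pool of clean ECG and noise records for online mixing
#'
#' Emulates the fixed clean corpus + noise-record setup used for online
#' augmentation: a set of clean 5 s templates (heart rates drawn from
#' 55-95 bpm) with exact beat annotations, and longer EM/MA/BW records that
#' are randomly cropped at batch time.
#'
#' @param n_clean Number of clean records.
#' @param duration_s Clean record duration (5 s windows by default).
#' @param fs Sampling rate (200 Hz).
#' @param n_noise Number of EM/MA noise records each.
#' @param noise_duration_s Noise record duration.
#' @param seed Integer seed.
#' @return A `corpus_pool` list.
#' @export
synth_corpus_pool <- function(n_clean = 40L, duration_s = 5, fs = 200,
                              n_noise = 12L, noise_duration_s = 12,
                              seed = 1L) {
  with_seed(seed, {
    hrs <- stats::runif(n_clean, 55, 95)
    clean <- lapply(seq_len(n_clean), function(i)
      generate_clean_ecg(duration_s, fs, hrs[i],
                         seed = sample.int(2^30, 1L)))
    em <- lapply(seq_len(n_noise), function(i)
      generate_noise("EM", noise_duration_s, fs, seed = sample.int(2^30, 1L)))
    ma <- lapply(seq_len(n_noise), function(i)
      generate_noise("MA", noise_duration_s, fs, seed = sample.int(2^30, 1L)))
    bw <- lapply(seq_len(n_noise), function(i)
      generate_noise("BW", noise_duration_s, fs, seed = sample.int(2^30, 1L)))
    structure(list(clean = clean, em = em, ma = ma, bw = bw,
                   fs = fs, n = as.integer(duration_s * fs)),
              class = "corpus_pool")
  })
}

#' Draw one training batch with online noise augmentation
#'
#' Samples categories from `category_mix`, picks random clean templates and
#' noise records from the pool, and synthesizes fresh noisy windows at
#' category-controlled SNR. Deterministic given `step_seed`.
#'
#' @param pool A [synth_corpus_pool()].
#' @param batch_size Number of samples.
#' @param policy A [mixing_policy()].
#' @param category_mix Proportions over (Good, Medium, Bad).
#' @param step_seed Integer seed for this batch.
#' @return List with matrices `x` (noisy input), `target` (clean),
#'   `level` (weak labels), vector `y` (categories), `snr_db`, and the
#'   per-sample list `samples`.
#' @export
make_batch <- function(pool, batch_size, policy = mixing_policy(),
                       category_mix = c(1, 1, 1) / 3, step_seed = 1L) {
  n <- pool$n
  with_seed(step_seed, {
    ys <- sample.int(3L, batch_size, replace = TRUE, prob = category_mix)
    seeds <- sample.int(2^30, batch_size)
    picks_c <- sample.int(length(pool$clean), batch_size, replace = TRUE)
    picks_e <- sample.int(length(pool$em), batch_size, replace = TRUE)
    picks_m <- sample.int(length(pool$ma), batch_size, replace = TRUE)
    picks_b <- sample.int(length(pool$bw), batch_size, replace = TRUE)
    samples <- lapply(seq_len(batch_size), function(i) {
      cl <- pool$clean[[picks_c[i]]]
      synthesize_noisy_sample(cl$signal, cl$annotations, ys[i], policy,
                              em = pool$em[[picks_e[i]]],
                              ma = pool$ma[[picks_m[i]]],
                              bw = pool$bw[[picks_b[i]]],
                              seed = seeds[i])
    })
    list(x = t(vapply(samples, function(s) s$noisy$samples, numeric(n))),
         target = t(vapply(samples, function(s) s$clean$samples, numeric(n))),
         level = t(vapply(samples, function(s) s$noise_level, numeric(n))),
         y = ys,
         snr_db = vapply(samples, `[[`, 0, "snr_db"),
         samples = samples)
  })
}

adam_init <- function(pf) {
  list(m = lapply(pf, function(x) x * 0),
       v = lapply(pf, function(x) x * 0), t = 0L)
}

adam_step <- function(pf, gf, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(pf)) {
    g <- gf[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    pf[[nm]] <- pf[[nm]] - lr * (st$m[[nm]] / b1t) /
      (sqrt(st$v[[nm]] / b2t) + eps)
  }
  list(pf = pf, st = st)
}

rebuild_params <- function(params, pf) {
  for (nm in names(pf)) params <- set_by_path(params, nm, pf[[nm]])
  params
}

batch_losses <- function(model, batch, alpha, training = FALSE,
                         dropout_seed = NULL) {
  o <- model_forward(model, batch$x, training = training,
                     dropout_seed = dropout_seed)
  mask <- wavelet_importance_mask(batch$target)
  ld <- denoising_loss(o$denoised, batch$target, batch$y, mask = mask,
                       alpha = alpha, grad = training)
  lc <- classification_loss(batch$y, o$class_probs, grad = training)
  ll <- noise_level_loss(o$noise_level, batch$level, grad = training)
  list(o = o, ld = ld, lc = lc, ll = ll)
}

# Recalibrate batch-norm running statistics after training: plain average
# of batch means/variances over a few fresh batches, replacing the lagging
# exponential estimate so evaluation-mode normalization matches the weights.
bn_recalibrate <- function(model, pool, config, policy, n_batches = 6L) {
  mus1 <- vars1 <- mus2 <- vars2 <- NULL
  for (k in seq_len(n_batches)) {
    batch <- make_batch(pool, config$batch_size, policy,
                        config$category_mix,
                        step_seed = config$seed + 31L * k + 500000L)
    o <- model_forward(model, batch$x, training = TRUE,
                       dropout_seed = k)
    mus1 <- rbind(mus1, o$cache$bn1$cache$mu)
    vars1 <- rbind(vars1, o$cache$bn1$cache$var)
    mus2 <- rbind(mus2, o$cache$bn2$cache$mu)
    vars2 <- rbind(vars2, o$cache$bn2$cache$var)
  }
  model$state$bn1 <- list(mean = colMeans(mus1), var = colMeans(vars1))
  model$state$bn2 <- list(mean = colMeans(mus2), var = colMeans(vars2))
  model
}

#' Train the multi-task model with Adam and uncertainty weighting
#'
#' Optimizes the uncertainty-weighted sum of the three task losses; the
#' per-task log-uncertainties are trained jointly with the network. Weight
#' decay is applied to weight matrices (not biases, norms, or
#' uncertainties). After the last epoch the batch-norm running statistics
#' are recalibrated over a few fresh batches so evaluation-mode
#' normalization matches the final weights. Aborts with a diagnostic if the
#' loss turns non-finite.
#'
#' @param model An `ecg_model` from [build_model()].
#' @param pool A [synth_corpus_pool()].
#' @param config A [train_config()].
#' @param policy A [mixing_policy()].
#' @param verbose Print per-epoch losses?
#' @return List with `model` (trained; best validation checkpoint when
#'   `val_size > 0`, else final), `log` (per-epoch data frame with task
#'   losses and sigmas), and `log_sigma`.
#' @export
train_model <- function(model, pool, config = train_config(),
                        policy = mixing_policy(), verbose = FALSE) {
  pf <- flatten_params(model$params)
  log_sigma <- c(denoise = 0, cls = 0, level = 0)
  st <- adam_init(pf)
  st_sig <- adam_init(as.list(log_sigma))
  decay_ok <- grepl("\\.W[12o]?$|\\.W[qkv]$|\\.W$", names(pf))

  val_batch <- if (config$val_size > 0)
    make_batch(pool, config$val_size, policy, config$category_mix,
               step_seed = config$seed + 987654L) else NULL
  best_val <- Inf
  best_model <- NULL

  logs <- list()
  for (ep in seq_len(config$epochs)) {
    ep_l <- c(0, 0, 0); ep_tot <- 0
    for (stp in seq_len(config$steps_per_epoch)) {
      sseed <- config$seed + 7919L * ep + stp
      batch <- make_batch(pool, config$batch_size, policy,
                          config$category_mix, step_seed = sseed)
      r <- batch_losses(model, batch, config$alpha, training = TRUE,
                        dropout_seed = sseed + 13L)
      L <- c(r$ld$loss, r$lc$loss, r$ll$loss)
      tl <- total_loss(L, log_sigma, grad = TRUE)
      if (!is.finite(tl$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      G <- model_backward(model, r$o$cache,
                          d_denoised = tl$d_loss[1L] * r$ld$grad,
                          d_level = tl$d_loss[3L] * r$ll$grad,
                          d_logits = tl$d_loss[2L] * r$lc$grad_logits)
      gf <- flatten_params(G)[names(pf)]
      if (config$weight_decay > 0)
        for (i in which(decay_ok))
          gf[[i]] <- gf[[i]] + config$weight_decay * pf[[i]]
      up <- adam_step(pf, gf, st, config$lr)
      pf <- up$pf; st <- up$st
      ups <- adam_step(as.list(log_sigma), as.list(tl$d_log_sigma), st_sig,
                       config$lr)
      log_sigma <- unlist(ups$pf); st_sig <- ups$st
      model$params <- rebuild_params(model$params, pf)
      model$state <- r$o$state
      ep_l <- ep_l + L; ep_tot <- ep_tot + tl$loss
    }
    ep_l <- ep_l / config$steps_per_epoch
    ep_tot <- ep_tot / config$steps_per_epoch

    val_tot <- NA_real_
    if (!is.null(val_batch)) {
      rv <- batch_losses(model, val_batch, config$alpha, training = FALSE)
      val_tot <- total_loss(c(rv$ld, rv$lc, rv$ll), log_sigma)
      if (val_tot < best_val) { best_val <- val_tot; best_model <- model }
    }
    logs[[ep]] <- data.frame(epoch = ep, total = ep_tot,
                             denoise = ep_l[1L], cls = ep_l[2L],
                             level = ep_l[3L],
                             sigma_denoise = exp(log_sigma[1L]),
                             sigma_cls = exp(log_sigma[2L]),
                             sigma_level = exp(log_sigma[3L]),
                             val_total = val_tot)
    if (verbose)
      message(sprintf("epoch %d: total %.4f (den %.4f cls %.4f lvl %.4f)",
                      ep, ep_tot, ep_l[1L], ep_l[2L], ep_l[3L]))
  }
  out_model <- bn_recalibrate(best_model %||% model, pool, config, policy)
  list(model = out_model, log = do.call(rbind, logs),
       log_sigma = log_sigma)
}

#' Evaluate a model on a set of noisy samples
#'
#' Runs the forward pass over all samples, computes classification metrics
#' against the category labels and denoising metrics against the clean
#' references (pure-noise windows excluded), the latter also binned by
#' input SNR into the three evaluation bins \[-5, 3\], (3, 16) and
#' \[16, 18\] dB.
#'
#' @param model A trained `ecg_model`.
#' @param samples List of `noisy_sample` objects.
#' @param batch_size Forward batch size.
#' @return A `metrics_report`: list with `classification`, `denoising`
#'   (overall mean +- sd), `by_bin` (per-SNR-bin data frame), `y_pred`.
#' @export
evaluate_model <- function(model, samples, batch_size = 32L) {
  n <- length(samples)
  stopifnot(n >= 1L)
  len <- length(samples[[1L]]$noisy$samples)
  X <- t(vapply(samples, function(s) s$noisy$samples, numeric(len)))
  y <- vapply(samples, `[[`, 0L, "category")
  den <- matrix(0, n, len)
  y_pred <- integer(n)
  lvl <- matrix(0, n, len)
  for (i0 in seq(1L, n, by = batch_size)) {
    i1 <- min(n, i0 + batch_size - 1L)
    o <- model_forward(model, X[i0:i1, , drop = FALSE])
    den[i0:i1, ] <- o$denoised
    lvl[i0:i1, ] <- o$noise_level
    y_pred[i0:i1] <- max.col(o$class_probs)
  }
  cls <- classification_metrics(y, y_pred)

  usable <- which(!vapply(samples, function(s) isTRUE(s$pure_noise), TRUE))
  dn <- lapply(usable, function(i) {
    cl <- samples[[i]]$clean$samples
    before <- denoising_metrics(cl, samples[[i]]$noisy$samples)
    after <- denoising_metrics(cl, den[i, ])
    c(snr_mix = samples[[i]]$snr_db,   # EM+MA mixing SNR (BW excluded)
      snr_before = before$snr_db, snr_after = after$snr_db,
      prd = after$prd, rmse = after$rmse, cossim = after$cossim)
  })
  dn <- as.data.frame(do.call(rbind, dn))
  dn <- dn[is.finite(dn$snr_after) & is.finite(dn$snr_before), , drop = FALSE]
  summ <- function(v) c(mean = mean(v), sd = stats::sd(v))
  bins <- list(`-5..3 dB` = c(-5, 3), `3..16 dB` = c(3, 16),
               `16..18 dB` = c(16, 18))
  by_bin <- do.call(rbind, lapply(names(bins), function(bn) {
    r <- bins[[bn]]
    sel <- dn$snr_mix >= r[1L] & dn$snr_mix <= r[2L]
    if (!any(sel)) return(data.frame(bin = bn, n = 0L, snr_before = NA,
                                     snr_after = NA, prd = NA, rmse = NA,
                                     cossim = NA))
    data.frame(bin = bn, n = sum(sel),
               snr_before = mean(dn$snr_before[sel]),
               snr_after = mean(dn$snr_after[sel]),
               prd = mean(dn$prd[sel]), rmse = mean(dn$rmse[sel]),
               cossim = mean(dn$cossim[sel]))
  }))
  structure(list(
    classification = cls,
    denoising = lapply(dn, summ),
    by_bin = by_bin,
    y_pred = y_pred,
    noise_level = lvl
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n accuracy:", round(x$classification$accuracy, 4),
      " weighted F1:", round(x$classification$weighted[["f1"]], 4), "\n")
  print(x$by_bin, row.names = FALSE)
  invisible(x)
}

#' Plot an ECG trace with its noise-level graph as background heatmap
#'
#' Renders the waveform with the model's per-sample noise probability shown
#' as a color band behind the trace (darker = more likely unacceptable).
#'
#' @param x Numeric vector (or [ecg_signal]) of the trace.
#' @param noise_level Vector in \[0,1\], same length.
#' @param fs Sampling rate (used for the time axis).
#' @param main Plot title.
#' @return Invisibly, `NULL`; draws on the current device.
#' @export
plot_noise_level <- function(x, noise_level, fs = 200, main = "ECG noise level") {
  if (inherits(x, "ecg_signal")) { fs <- x$fs; x <- x$samples }
  stopifnot(length(x) == length(noise_level))
  tt <- (seq_along(x) - 1L) / fs
  graphics::plot(tt, x, type = "n", xlab = "time (s)", ylab = "mV",
                 main = main)
  usr <- graphics::par("usr")
  cols <- grDevices::rgb(1, 0.55, 0, alpha = pmin(pmax(noise_level, 0), 1) * 0.8)
  graphics::rect(tt - 0.5 / fs, usr[3L], tt + 0.5 / fs, usr[4L],
                 col = cols, border = NA)
  graphics::lines(tt, x, col = "black")
  invisible(NULL)
}
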