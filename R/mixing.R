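#' Mixing policy: SNR ranges per quality category and blend settings
#'
#' Category-to-SNR mapping for noisy-ECG synthesis. Only EM and MA noise
#' enter the SNR budget; baseline wander, which leaves waveform morphology
#' intact, is added outside it at a small fixed amplitude. SNR ranges are
#' Good \[16, 18\] dB, Medium \[5, 14\] dB, Bad \[-5, -3\] dB; the gaps
#' (14-16 and -3-5 dB) are never sampled, keeping categories well separated.
#'
#' @param snr_ranges Named list of length-2 dB ranges for `GOOD`, `MEDIUM`,
#'   `BAD`. Must be ordered GOOD > MEDIUM > BAD and non-overlapping.
#' @param include_bw Add baseline wander outside the SNR budget?
#' @param bw_amplitude BW standard deviation in mV (default 0.1).
#' @param blend_choices List of `(em, ma)` power-weight pairs; one is drawn
#'   uniformly per sample (EM-only, MA-only, or an equal-power blend).
#' @return A `mixing_policy` object.
#' @export
mixing_policy <- function(snr_ranges = list(GOOD = c(16, 18),
                                            MEDIUM = c(5, 14),
                                            BAD = c(-5, -3)),
                          include_bw = TRUE, bw_amplitude = 0.1,
                          blend_choices = list(c(1, 0), c(0, 1), c(.5, .5))) {
  stopifnot(all(c("GOOD", "MEDIUM", "BAD") %in% names(snr_ranges)))
  r <- snr_ranges
  if (!(r$GOOD[1] > r$MEDIUM[2] && r$MEDIUM[1] > r$BAD[2]))
    stop("SNR ranges must be non-overlapping and ordered GOOD > MEDIUM > BAD")
  structure(list(snr_ranges = r, include_bw = include_bw,
                 bw_amplitude = bw_amplitude, blend_choices = blend_choices),
            class = "mixing_policy")
}

#' Scale a noise signal to hit an exact target SNR against a clean signal
#'
#' Returns `k * noise` with `k` chosen so that
#' `10 * log10(sum(clean^2) / sum((k*noise)^2))` equals `target_snr_db` to
#' machine precision.
#'
#' @param clean,noise [ecg_signal]s of equal length and sampling rate.
#' @param target_snr_db Target SNR in dB.
#' @return The scaled noise as an [ecg_signal].
#' @export
scale_noise_to_snr <- function(clean, noise, target_snr_db) {
  stopifnot(inherits(clean, "ecg_signal"), inherits(noise, "ecg_signal"))
  if (length(clean$samples) != length(noise$samples))
    stop("'clean' and 'noise' must have equal length")
  if (clean$fs != noise$fs)
    stop("'clean' and 'noise' must share a sampling rate")
  ps <- sumsq(clean$samples)
  pn <- sumsq(noise$samples)
  if (ps <= 0) stop("clean signal has zero power")
  if (pn <= 0) stop("noise signal has zero power")
  k <- sqrt(ps / (pn * 10^(target_snr_db / 10)))
  ecg_signal(k * noise$samples, noise$fs)
}

#' Realized SNR between a clean reference and its noisy version
#' @param clean,noisy Numeric vectors or [ecg_signal]s of equal length.
#' @return SNR in dB (`Inf` when the residual is zero).
#' @export
realized_snr <- function(clean, noisy) {
  x <- if (inherits(clean, "ecg_signal")) clean$samples else as.numeric(clean)
  y <- if (inherits(noisy, "ecg_signal")) noisy$samples else as.numeric(noisy)
  r <- sumsq(y - x)
  if (r == 0) return(Inf)
  10 * log10(sumsq(x) / r)
}

random_crop <- function(sig, n) {
  m <- length(sig$samples)
  if (m < n) stop("noise record shorter than the clean window")
  if (m == n) return(sig$samples)
  s0 <- sample.int(m - n + 1L, 1L)
  sig$samples[s0:(s0 + n - 1L)]
}

#' Synthesize one noisy training sample at a category-controlled SNR
#'
#' Draws a target SNR uniformly from the policy range of `category`, blends
#' EM and MA noise with per-sample random blend weights, scales the blend so
#' the realized EM+MA SNR hits the target exactly, and optionally adds
#' baseline wander outside the SNR budget. For `BAD`, with probability
#' `pure_noise_prob`, the clean content is dropped entirely and the window is
#' pure noise (emulating uninterpretable-noise segments used as the Bad
#' class); such windows carry all-ones noise-level labels.
#'
#' @param clean Clean [ecg_signal] (the model's reconstruction target).
#' @param annotations [beat_annotations] for `clean`.
#' @param category Quality category (1/2/3 or "GOOD"/"MEDIUM"/"BAD").
#' @param policy A [mixing_policy()].
#' @param em,ma Noise [ecg_signal]s at least as long as `clean` (randomly
#'   cropped).
#' @param bw Optional BW [ecg_signal]; generated on the fly if `NULL` and
#'   `policy$include_bw` is `TRUE`.
#' @param seed Integer seed; deterministic given all arguments.
#' @param pure_noise_prob Probability that a BAD sample is pure noise.
#' @param snr_thr,corr_thr Thresholds forwarded to
#'   [compute_rr_noise_labels()].
#'
#' @return A `noisy_sample`: list with `clean`, `noisy` ([ecg_signal]s),
#'   `category` (integer code), `noise_level` (length-n vector in \[0,1\]),
#'   `snr_db` (realized EM+MA SNR), and `r_peaks`.
#' @export
synthesize_noisy_sample <- function(clean, annotations, category, policy,
                                    em, ma, bw = NULL, seed = 1L,
                                    pure_noise_prob = 0.3,
                                    snr_thr = 5, corr_thr = 0.8) {
  stopifnot(inherits(clean, "ecg_signal"), inherits(policy, "mixing_policy"))
  code <- quality_category(category)
  key <- attr(code, "label")
  n <- length(clean$samples)
  rng <- policy$snr_ranges[[key]]

  with_seed(seed, {
    target <- stats::runif(1L, rng[1], rng[2])
    wts <- policy$blend_choices[[sample.int(length(policy$blend_choices), 1L)]]
    # crop until the window carries noise energy (EM is sparse, so an
    # unlucky crop can be all-zero); shift weight to the other component
    # if one record is degenerate over the whole window
    crop_nonzero <- function(sig) {
      for (i in seq_len(20L)) {
        v <- random_crop(sig, n)
        if (sqrt(sumsq(v)) > 1e-9) return(v)
      }
      NULL
    }
    em_c <- if (wts[1] > 0) crop_nonzero(em) else NULL
    ma_c <- if (wts[2] > 0) crop_nonzero(ma) else NULL
    if (is.null(em_c) && wts[1] > 0) { wts <- c(0, 1); ma_c <- ma_c %||% crop_nonzero(ma) }
    if (is.null(ma_c) && wts[2] > 0) { wts <- c(1, 0); em_c <- em_c %||% crop_nonzero(em) }
    if (is.null(em_c) && is.null(ma_c))
      stop("both noise records have zero power over the window")
    unit <- function(v) v / sqrt(sumsq(v))
    blend <- numeric(n)
    if (wts[1] > 0) blend <- blend + sqrt(wts[1]) * unit(em_c)
    if (wts[2] > 0) blend <- blend + sqrt(wts[2]) * unit(ma_c)
    blend_sig <- ecg_signal(blend, clean$fs)

    pure <- code == QUALITY_LEVELS[["BAD"]] &&
      stats::runif(1L) < pure_noise_prob

    scaled <- scale_noise_to_snr(clean, blend_sig, target)
    bw_add <- numeric(n)
    if (policy$include_bw) {
      if (is.null(bw)) {
        bw <- generate_noise("BW", n / clean$fs, clean$fs,
                             seed = sample.int(2^30, 1L))
        bw_add <- policy$bw_amplitude * bw$samples
      } else {
        bw_c <- random_crop(bw, n)
        bw_add <- policy$bw_amplitude * bw_c / max(stats::sd(bw_c), 1e-12)
      }
    }

    if (pure) {
      # pure-noise Bad window: noise at clean-comparable power, no clean part
      amp <- sqrt(sumsq(clean$samples) / n)
      noisy <- ecg_signal(amp * blend / stats::sd(blend) + bw_add, clean$fs)
      return(structure(
        list(clean = clean, noisy = noisy, category = as.integer(code),
             noise_level = rep(1, n),
             snr_db = rng[1],  # nominal: no clean reference exists
             r_peaks = integer(0), pure_noise = TRUE),
        class = "noisy_sample"))
    }

    noisy <- ecg_signal(clean$samples + scaled$samples + bw_add, clean$fs)
    smp <- structure(
      list(clean = clean, noisy = noisy, category = as.integer(code),
           noise_level = NULL,
           snr_db = realized_snr(clean$samples,
                                 clean$samples + scaled$samples),
           r_peaks = annotations$r_peaks, pure_noise = FALSE),
      class = "noisy_sample")
    smp$noise_level <- compute_rr_noise_labels(smp, snr_thr = snr_thr,
                                               corr_thr = corr_thr)
    smp
  })
}

#' @export
print.noisy_sample <- function(x, ...) {
  cat(sprintf("<noisy_sample> category %d, %d samples, SNR %.2f dB, %.0f%% labeled noisy\n",
              x$category, length(x$noisy$samples), x$snr_db,
              100 * mean(x$noise_level)))
  invisible(x)
}

#' Weak per-point noise-level labels from per-R-R SNR and correlation
#'
#' Splits the window into half-open R-R segments `[r_k, r_{k+1})` (0-based
#' indices). A segment is labeled 1 (unacceptable noise, fiducial points
#' indistinct) when its local SNR falls below `snr_thr` dB or the Pearson
#' correlation between clean and noisy falls below `corr_thr`; otherwise 0.
#' Samples before the first and after the last R peak inherit the adjacent
#' segment's label. With fewer than two R peaks the whole window is labeled
#' by its global SNR/correlation, with a warning.
#'
#' @param sample A `noisy_sample` (needs `clean`, `noisy`, `r_peaks`).
#' @param snr_thr Local SNR threshold in dB (default 5, the Medium floor).
#' @param corr_thr Pearson correlation threshold (default 0.8).
#' @return Numeric vector in `{0,1}`, same length as the signal.
#' @export
compute_rr_noise_labels <- function(sample, snr_thr = 5, corr_thr = 0.8) {
  x <- sample$clean$samples
  y <- sample$noisy$samples
  n <- length(x)
  stopifnot(length(y) == n)
  r <- as.integer(sample$r_peaks)

  seg_bad <- function(i0, i1) {  # 1-based inclusive range
    xs <- x[i0:i1]; ys <- y[i0:i1]
    res <- sumsq(ys - xs)
    snr <- if (res == 0) Inf else 10 * log10(sumsq(xs) / res)
    cc <- if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      if (res == 0) 1 else 0
    } else stats::cor(xs, ys)
    as.numeric(snr < snr_thr || cc < corr_thr)
  }

  if (length(r) < 2L) {
    warning("fewer than 2 R peaks; labeling whole window globally")
    return(rep(seg_bad(1L, n), n))
  }

  lab <- numeric(n)
  for (k in seq_len(length(r) - 1L)) {
    i0 <- r[k] + 1L          # 0-based r to 1-based index
    i1 <- r[k + 1L]          # half-open [r_k, r_{k+1})
    lab[i0:i1] <- seg_bad(i0, i1)
  }
  if (r[1L] > 0L) lab[1:r[1L]] <- lab[r[1L] + 1L]
  if (r[length(r)] < n - 1L) lab[(r[length(r)] + 1L):n] <- lab[r[length(r)]]
  lab
}
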