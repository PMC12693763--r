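#' Preprocessing configuration
#'
#' Defaults for the classical preprocessing chain: flat-line detection,
#' cascaded median-filter baseline removal (0.2 s then 0.6 s windows),
#' zero-phase 1-40 Hz band-pass, Savitzky-Golay smoothing, isoline
#' correction, and resampling to 200 Hz.
#'
#' @param std_thr Flat-line standard-deviation threshold in mV.
#' @param min_peaks Minimum detected-peak count; `NULL` means
#'   `floor(duration_s / 2)` (one peak per 2 s, i.e. 30 bpm).
#' @param median_windows Median-filter window lengths in seconds.
#' @param bandpass Band-pass corner frequencies in Hz.
#' @param savgol_window Savitzky-Golay window in seconds.
#' @param savgol_order Savitzky-Golay polynomial order.
#' @param target_fs Model sampling rate in Hz.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(std_thr = 0.01, min_peaks = NULL,
                              median_windows = c(0.2, 0.6),
                              bandpass = c(1, 40),
                              savgol_window = 0.031, savgol_order = 3,
                              target_fs = 200) {
  stopifnot(all(median_windows > 0),
            bandpass[1] > 0, bandpass[1] < bandpass[2],
            bandpass[2] < target_fs / 2)
  structure(list(std_thr = std_thr, min_peaks = min_peaks,
                 median_windows = median_windows, bandpass = bandpass,
                 savgol_window = savgol_window, savgol_order = savgol_order,
                 target_fs = target_fs),
            class = "preprocess_config")
}

#' Detect a flat-line (lead-off) window
#'
#' `TRUE` when the standard deviation falls below `std_thr` or fewer peaks
#' than `min_peaks` are detected — both symptoms of electrode detachment or
#' an absent rhythm.
#'
#' @param x An [ecg_signal].
#' @param config A [preprocess_config()].
#' @return Logical flag.
#' @export
detect_flat_line <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "ecg_signal"))
  s <- stats::sd(x$samples)
  if (s < config$std_thr) return(TRUE)
  min_peaks <- config$min_peaks %||% max(1L, floor(duration(x) / 2))
  pk <- tryCatch(detect_rpeaks(x), error = function(e) NULL)
  npk <- if (is.null(pk)) 0L else length(pk$r_peaks)
  npk < min_peaks
}

#' Remove baseline wander with cascaded median filters
#'
#' Two median filters (0.2 s then 0.6 s windows, forced to odd sample
#' counts) estimate the baseline, which is subtracted. Length and sampling
#' rate are preserved.
#'
#' @param x An [ecg_signal].
#' @param config A [preprocess_config()].
#' @return Baseline-corrected [ecg_signal].
#' @export
remove_baseline <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "ecg_signal"))
  w1 <- odd_window(config$median_windows[1], x$fs)
  w2 <- odd_window(config$median_windows[2], x$fs)
  if (length(x$samples) <= max(w1, w2))
    stop("signal shorter than the longer median window")
  base <- stats::runmed(x$samples, w1, endrule = "median")
  base <- stats::runmed(base, w2, endrule = "median")
  ecg_signal(x$samples - base, x$fs, x$start_time)
}

#' Band-pass, smooth, and correct the isoline
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass at 1-40 Hz,
#' Savitzky-Golay smoothing (31 ms window, order 3 by default), then mean
#' subtraction (electrical isoline correction).
#'
#' @param x An [ecg_signal] with `fs > 80` Hz.
#' @param config A [preprocess_config()].
#' @return Filtered [ecg_signal] of the same length and rate.
#' @export
bandpass_smooth <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "ecg_signal"))
  ny <- x$fs / 2
  if (config$bandpass[2] >= ny)
    stop("band-pass upper edge must be below Nyquist")
  bf <- signal::butter(4, config$bandpass / ny, type = "pass")
  v <- signal::filtfilt(bf, x$samples)
  w <- odd_window(config$savgol_window, x$fs)
  w <- max(w, config$savgol_order + 2L + ((config$savgol_order + 1L) %% 2L))
  if (w %% 2L == 0L) w <- w + 1L
  v <- signal::sgolayfilt(v, p = config$savgol_order, n = w)
  v <- v - mean(v)
  ecg_signal(v, x$fs, x$start_time)
}

#' Resample a signal to a target rate
#'
#' Fourier-domain resampling; the new length is
#' `round(length * target_fs / fs)`.
#'
#' @param x An [ecg_signal].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return Resampled [ecg_signal].
#' @export
resample_to <- function(x, target_fs) {
  stopifnot(inherits(x, "ecg_signal"))
  if (!is.numeric(target_fs) || target_fs <= 0)
    stop("'target_fs' must be positive")
  if (target_fs == x$fs) return(x)
  n_old <- length(x$samples)
  n_new <- as.integer(round(n_old * target_fs / x$fs))
  v <- fft_resample(x$samples, n_new)
  ecg_signal(v, target_fs, x$start_time)
}

# Length-changing resampling via FFT bin truncation/zero-padding.
fft_resample <- function(x, n_new) {
  n <- length(x)
  if (n_new == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_new)
  keep <- min(n, n_new)
  h <- floor(keep / 2)
  Y[1:(h + 1L)] <- X[1:(h + 1L)]
  if (h > 0) Y[(n_new - h + 1L):n_new] <- X[(n - h + 1L):n]
  if (keep %% 2L == 0L && h > 0) {
    # split the shared Nyquist bin symmetrically
    if (n_new < n) {
      Y[h + 1L] <- (X[h + 1L] + X[n - h + 1L]) / 2
    } else {
      Y[h + 1L] <- X[h + 1L] / 2
      Y[n_new - h + 1L] <- X[h + 1L] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n * 1
}

#' Detect R peaks with the Pan-Tompkins algorithm plus local correction
#'
#' Classic chain: 5-15 Hz band-pass, differentiation, squaring, 150 ms
#' moving-window integration, and adaptive signal/noise thresholds with
#' search-back, followed by an adaptive correction that snaps each detection
#' to the largest absolute amplitude of the band-passed signal within
#' +-50 ms. A 200 ms refractory period is enforced.
#'
#' @param x An [ecg_signal] with `fs >= 100` Hz and duration >= 2 s.
#' @return A [beat_annotations] with 0-based R-peak indices.
#' @export
detect_rpeaks <- function(x) {
  stopifnot(inherits(x, "ecg_signal"))
  fs <- x$fs
  if (fs < 100) stop("'fs' must be >= 100 Hz")
  n <- length(x$samples)
  if (n / fs < 2) stop("signal must be at least 2 s long")

  v <- x$samples - mean(x$samples)
  if (stats::sd(v) == 0) return(beat_annotations(integer(0)))
  ny <- fs / 2
  bf <- signal::butter(2, c(5, 15) / ny, type = "pass")
  bp <- signal::filtfilt(bf, v)
  dv <- c(0, diff(bp)) * fs
  sq <- dv^2
  wi <- max(3L, as.integer(round(0.150 * fs)))
  mwi <- stats::filter(sq, rep(1 / wi, wi), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  refr <- as.integer(round(0.200 * fs))
  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand)) return(beat_annotations(integer(0)))

  spki <- max(mwi[seq_len(min(n, 2L * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, 2L * fs))]) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  last <- -Inf
  for (p in cand) {
    if (p - last < refr) next
    if (mwi[p] >= thr1) {
      peaks <- c(peaks, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      last <- p
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  # search-back over long gaps with the halved threshold
  if (length(peaks) >= 2L) {
    rr_mean <- mean(diff(peaks))
    add <- integer(0)
    gaps <- which(diff(peaks) > 1.66 * rr_mean)
    for (g in gaps) {
      lo <- peaks[g] + refr; hi <- peaks[g + 1L] - refr
      if (hi <= lo) next
      seg <- cand[cand > lo & cand < hi]
      seg <- seg[mwi[seg] >= thr1 / 2]
      if (length(seg)) add <- c(add, seg[which.max(mwi[seg])])
    }
    peaks <- sort(unique(c(peaks, add)))
  }

  # adaptive correction: snap to the band-passed extremum within +-50 ms
  half <- as.integer(round(0.050 * fs))
  snapped <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, 0L)
  snapped <- sort(unique(snapped))
  if (length(snapped) > 1L)
    snapped <- snapped[c(TRUE, diff(snapped) >= refr)]
  beat_annotations(snapped - 1L, n = n)  # back to 0-based
}

#' Run the full preprocessing chain
#'
#' Baseline removal, band-pass + smoothing + isoline correction, resampling
#' to the target rate, and R-peak detection.
#'
#' @param x An [ecg_signal].
#' @param config A [preprocess_config()].
#' @return List with `signal` (processed [ecg_signal]), `annotations`
#'   ([beat_annotations]), and `flat_line` (logical).
#' @export
preprocess_ecg <- function(x, config = preprocess_config()) {
  flat <- detect_flat_line(x, config)
  v <- remove_baseline(x, config)
  v <- bandpass_smooth(v, config)
  v <- resample_to(v, config$target_fs)
  ann <- if (flat) beat_annotations(integer(0)) else detect_rpeaks(v)
  list(signal = v, annotations = ann, flat_line = flat)
}
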