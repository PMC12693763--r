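#' Uniformly sampled single-lead ECG signal
#'
#' Lightweight container for a uniformly sampled 1-D waveform in millivolts.
#'
#' @param samples Numeric vector of sample values (mV). Must be finite and
#'   of length at least 1.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return An object of class `ecg_signal`: a list with elements `samples`,
#'   `fs` and `start_time`.
#' @examples
#' s <- ecg_signal(sin(2 * pi * 1 * seq(0, 1, by = 1 / 200)), fs = 200)
#' duration(s)
#' @export
ecg_signal <- function(samples, fs, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("'samples' must have length >= 1")
  if (!all(is.finite(samples)))
    stop("'samples' must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         start_time = as.numeric(start_time)),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.3f s), range [%.3f, %.3f] mV\n",
              length(x$samples), x$fs, duration(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' Duration of a signal in seconds
#' @param x An `ecg_signal`.
#' @return Duration in seconds (`length / fs`).
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "ecg_signal"))
  length(x$samples) / x$fs
}

#' Beat annotations: R peaks and optional fiducial points
#'
#' @param r_peaks Integer vector of 0-based R-peak sample indices, strictly
#'   increasing.
#' @param fiducials Optional data frame with one row per beat and integer
#'   columns `p_onset`, `qrs_onset`, `r_peak`, `qrs_offset`, `t_offset`
#'   (0-based sample indices; `NA` marks an absent wave). Within each beat
#'   the present indices must be ordered.
#' @param n Optional signal length used to bound-check indices.
#'
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(r_peaks, fiducials = NULL, n = NULL) {
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) > 1L && any(diff(r_peaks) <= 0L))
    stop("'r_peaks' must be strictly increasing")
  if (any(r_peaks < 0L))
    stop("'r_peaks' must be non-negative 0-based indices")
  if (!is.null(n) && length(r_peaks) && any(r_peaks > n - 1L))
    stop("'r_peaks' out of signal bounds")
  if (!is.null(fiducials)) {
    fiducials <- as.data.frame(fiducials)
    need <- c("p_onset", "qrs_onset", "r_peak", "qrs_offset", "t_offset")
    if (!all(need %in% names(fiducials)))
      stop("'fiducials' must have columns ", paste(need, collapse = ", "))
    for (i in seq_len(nrow(fiducials))) {
      v <- unlist(fiducials[i, need])
      v <- v[!is.na(v)]
      if (length(v) > 1L && any(diff(v) < 0))
        stop("fiducials out of order in beat ", i)
    }
  }
  structure(list(r_peaks = r_peaks, fiducials = fiducials),
            class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d R peaks%s\n", length(x$r_peaks),
              if (is.null(x$fiducials)) "" else
                sprintf(", fiducials for %d beats", nrow(x$fiducials))))
  invisible(x)
}

#' Noise kinds
#'
#' The three ambulatory ECG noise types: baseline wander (`"BW"`, 0.05-1 Hz
#' drift), electrode-motion artifact (`"EM"`, transient 300-500 ms baseline
#' shifts), and muscle artifact (`"MA"`, broadband EMG-like interference).
#' @export
NOISE_KINDS <- c("BW", "EM", "MA")

#' Signal quality categories
#'
#' Three-level quality with fixed integer codes: Good = 1, Medium = 2,
#' Bad = 3. Good signals carry clear P-QRS-T morphology (mixing SNR >= 16 dB),
#' Medium signals retain rhythm but not morphology (5-14 dB), Bad signals have
#' no clinical value (<= -3 dB).
#' @export
QUALITY_LEVELS <- c(GOOD = 1L, MEDIUM = 2L, BAD = 3L)

#' Validate and normalize a quality category
#' @param category Either an integer code in 1:3 or one of
#'   `"GOOD"`, `"MEDIUM"`, `"BAD"` (case-insensitive).
#' @return Integer code in 1:3 with a `label` attribute.
#' @export
quality_category <- function(category) {
  if (is.character(category)) {
    key <- toupper(category)
    if (!key %in% names(QUALITY_LEVELS))
      stop("unknown quality category: ", category)
    code <- QUALITY_LEVELS[[key]]
  } else {
    code <- as.integer(category)
    if (!code %in% QUALITY_LEVELS)
      stop("quality code must be in 1:3")
  }
  structure(code, label = names(QUALITY_LEVELS)[code])
}
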