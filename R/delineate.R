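#' Wavelet ECG delineation with the db6 DWT
#'
#' Runs a multi-level periodized db6 decomposition and locates per-beat
#' fiducial points. QRS onset/offset come from the envelope of the
#' mid-frequency detail reconstructions (levels 2-3, roughly 12-50 Hz at
#' 200 Hz), thresholded at a fraction of the beat-local envelope maximum
#' with a floor of three scale-wise median absolute deviations. P and T
#' boundaries are found on the low-pass approximation (details 1-3 removed)
#' as threshold crossings around the local wave peak. Waves that do not rise
#' above the noise floor are reported as absent (`NA`), never fabricated.
#'
#' @param x An [ecg_signal] (preprocessed, baseline-free).
#' @param annotations [beat_annotations] with at least one R peak.
#' @param p_min_amp,t_min_amp Minimum wave amplitudes (mV) above the local
#'   baseline for a P/T wave to be reported.
#' @return A data frame of class `fiducial_points` with 0-based integer
#'   columns `p_onset`, `qrs_onset`, `r_peak`, `qrs_offset`, `t_offset`
#'   (`NA` = absent), one row per beat.
#' @export
delineate_dwt <- function(x, annotations, p_min_amp = 0.04,
                          t_min_amp = 0.05) {
  stopifnot(inherits(x, "ecg_signal"), inherits(annotations, "beat_annotations"))
  r <- annotations$r_peaks
  if (!length(r)) stop("at least one R peak is required")
  v <- x$samples
  n <- length(v)
  fs <- x$fs

  w <- dwt_db6(v, levels = 4L)
  nd <- length(w$details)
  D <- lapply(seq_len(nd), function(l) dwt_detail_reconstruction(w, l))
  e_qrs <- (if (nd >= 2L) abs(D[[2L]]) else abs(D[[1L]])) +
    (if (nd >= 3L) abs(D[[3L]]) else 0)
  # low-pass body of the signal: remove detail levels 1-3 (> ~12 Hz)
  lp <- v
  for (l in seq_len(min(3L, nd))) lp <- lp - D[[l]]

  mad_qrs <- stats::mad(e_qrs)
  ms <- function(t) as.integer(round(t * fs))

  out <- data.frame(p_onset = NA_integer_, qrs_onset = NA_integer_,
                    r_peak = as.integer(r), qrs_offset = NA_integer_,
                    t_offset = NA_integer_)
  for (b in seq_along(r)) {
    rp <- r[b] + 1L  # 1-based
    lo <- max(1L, rp - ms(0.080)); hi <- min(n, rp + ms(0.080))
    loc_max <- max(e_qrs[lo:hi])
    thr_q <- max(0.25 * loc_max, 3 * mad_qrs)
    above <- which(e_qrs[lo:hi] >= thr_q)
    if (length(above) && loc_max > 6 * mad_qrs) {
      on <- lo + above[1L] - 1L
      off <- lo + above[length(above)] - 1L
      if (on < rp) out$qrs_onset[b] <- on - 1L
      if (off > rp) out$qrs_offset[b] <- off - 1L
    }

    # baseline estimated from the window edges (outside the wave body)
    edge_base <- function(seg) {
      k <- max(2L, as.integer(round(0.15 * length(seg))))
      stats::median(c(seg[seq_len(k)], seg[(length(seg) - k + 1L):length(seg)]))
    }

    # T wave: low-pass bump after the QRS
    t0 <- min(n, rp + ms(0.100)); t1 <- min(n, rp + ms(0.420))
    if (t1 > t0 + 4L) {
      seg <- lp[t0:t1]
      base <- edge_base(seg)
      pk_rel <- which.max(abs(seg - base))
      amp <- abs(seg[pk_rel] - base)
      if (amp > t_min_amp) {
        pk <- t0 + pk_rel - 1L
        after <- abs(lp[pk:t1] - base)
        cross <- which(after >= 0.15 * amp)
        out$t_offset[b] <- pk + cross[length(cross)] - 1L - 1L
      }
    }

    # P wave: low-pass bump ending well before the QRS onset
    p1 <- (if (!is.na(out$qrs_onset[b])) out$qrs_onset[b] + 1L else
      rp - ms(0.055)) - ms(0.040)
    p0 <- max(1L, rp - ms(0.280))
    if (p1 > p0 + 4L) {
      seg <- lp[p0:p1]
      base <- edge_base(seg)
      pk_rel <- which.max(abs(seg - base))
      amp <- abs(seg[pk_rel] - base)
      k_edge <- max(2L, as.integer(round(0.15 * length(seg))))
      interior <- pk_rel > k_edge && pk_rel <= length(seg) - k_edge
      if (amp > p_min_amp && interior) {
        pk <- p0 + pk_rel - 1L
        before <- abs(lp[p0:pk] - base)
        cross <- which(before >= 0.15 * amp)
        if (length(cross))
          out$p_onset[b] <- p0 + cross[1L] - 1L - 1L
      }
    }
  }
  class(out) <- c("fiducial_points", "data.frame")
  out
}
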