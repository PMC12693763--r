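#' Default morphology parameters for the clean-ECG generator
#'
#' The clean generator lays a Gaussian-bump P-QRS-T template on an RR grid.
#' Each wave is a Gaussian with amplitude (mV), center offset from the R peak
#' (s) and width (s, standard deviation). Defaults give a lead-I-like beat
#' with ~1 mV R wave and ~90 ms QRS.
#'
#' @param r_amp,p_amp,q_amp,s_amp,t_amp Wave amplitudes in mV.
#' @param rr_jitter_sd Beat-to-beat RR jitter standard deviation in seconds.
#' @return A list of morphology parameters.
#' @export
ecg_morphology <- function(r_amp = 1.0, p_amp = 0.12, q_amp = -0.15,
                           s_amp = -0.20, t_amp = 0.30,
                           rr_jitter_sd = 0.02) {
  list(
    waves = data.frame(
      wave  = c("P", "Q", "R", "S", "T"),
      amp   = c(p_amp, q_amp, r_amp, s_amp, t_amp),
      mu    = c(-0.200, -0.030, 0.000, 0.030, 0.250),
      sigma = c(0.025, 0.008, 0.010, 0.008, 0.045)
    ),
    rr_jitter_sd = rr_jitter_sd
  )
}

#' Generate a clean synthetic ECG with known beat annotations
#'
#' Produces a quasi-periodic single-lead ECG by summing a Gaussian-bump
#' P-QRS-T template at R-peak times laid on an RR grid with Gaussian
#' beat-to-beat jitter. R-peak positions (and per-beat fiducials derived from
#' the template geometry) are returned as exact ground truth.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @param heart_rate_bpm Mean heart rate, 30-220 bpm.
#' @param morphology Parameter list from [ecg_morphology()].
#' @param seed Integer seed; the generator is deterministic given its
#'   arguments.
#'
#' @return A list with elements `signal` ([ecg_signal]) and `annotations`
#'   ([beat_annotations] including a per-beat fiducial table).
#' @examples
#' g <- generate_clean_ecg(5, 200, 60, seed = 1)
#' length(g$signal$samples)  # 1000
#' @export
generate_clean_ecg <- function(duration_s, fs, heart_rate_bpm = 70,
                               morphology = ecg_morphology(), seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("'duration_s' must be positive")
  if (!is.numeric(fs) || fs <= 0)
    stop("'fs' must be positive")
  if (heart_rate_bpm < 30 || heart_rate_bpm > 220)
    stop("'heart_rate_bpm' must be in [30, 220]")

  n <- as.integer(round(duration_s * fs))
  rr <- 60 / heart_rate_bpm
  w <- morphology$waves

  r_times <- with_seed(seed, {
    # first beat placed so a full P wave fits; jittered RR thereafter
    t0 <- 0.30 * rr + 0.1
    ts <- t0
    repeat {
      dt <- rr + stats::rnorm(1L, 0, morphology$rr_jitter_sd)
      dt <- max(dt, 0.25)  # refractory floor
      nt <- ts[length(ts)] + dt
      if (nt > duration_s + rr) break
      ts <- c(ts, nt)
    }
    ts
  })

  tgrid <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (rt in r_times) {
    for (k in seq_len(nrow(w))) {
      mu <- rt + w$mu[k]
      # restrict to +-5 sigma support for speed
      lo <- max(1L, floor((mu - 5 * w$sigma[k]) * fs) + 1L)
      hi <- min(n, ceiling((mu + 5 * w$sigma[k]) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + w$amp[k] * exp(-0.5 * ((tgrid[idx] - mu) / w$sigma[k])^2)
    }
  }

  r_idx <- as.integer(round(r_times * fs))
  keep <- r_idx >= 0L & r_idx <= n - 1L
  r_idx <- r_idx[keep]
  r_kept <- r_times[keep]

  clampNA <- function(v) ifelse(v >= 0L & v <= n - 1L, v, NA_integer_)
  mu_of <- function(wave) w$mu[w$wave == wave]
  sig_of <- function(wave) w$sigma[w$wave == wave]
  fid <- data.frame(
    p_onset    = clampNA(as.integer(round((r_kept + mu_of("P") - 2 * sig_of("P")) * fs))),
    qrs_onset  = clampNA(as.integer(round((r_kept + mu_of("Q") - 2 * sig_of("Q")) * fs))),
    r_peak     = r_idx,
    qrs_offset = clampNA(as.integer(round((r_kept + mu_of("S") + 2 * sig_of("S")) * fs))),
    t_offset   = clampNA(as.integer(round((r_kept + mu_of("T") + 2 * sig_of("T")) * fs)))
  )
  if (morphology$waves$amp[morphology$waves$wave == "P"] == 0)
    fid$p_onset <- NA_integer_

  list(signal = ecg_signal(x, fs),
       annotations = beat_annotations(r_idx, fiducials = fid, n = n))
}

#' Generate one of the three ambulatory ECG noise types
#'
#' * `"BW"` — baseline wander: a sum of random sinusoids confined to the
#'   0.05-1 Hz band (slow drifts from respiration and body movement).
#' * `"EM"` — electrode-motion artifact: sparse transient baseline-shift
#'   events, each lasting 300-500 ms, with amplitude a configurable multiple
#'   of a reference ECG peak-to-peak (default 2x), random sign per event.
#' * `"MA"` — muscle artifact: zero-mean broadband stochastic noise with the
#'   bulk of its power overlapping the 1-40 Hz ECG band plus a weaker
#'   high-frequency component.
#'
#' BW and MA outputs are normalized to unit standard deviation (SNR mixing
#' rescales them anyway); EM keeps its physical amplitude convention of
#' `em_amp_mult * ref_p2p` mV per event so the exceeds-peak-to-peak property
#' holds for standalone use.
#'
#' @param kind One of `"BW"`, `"EM"`, `"MA"`.
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed (deterministic output).
#' @param em_occupancy Target fraction of samples covered by EM events.
#' @param em_amp_mult EM event amplitude as a multiple of `ref_p2p`.
#' @param ref_p2p Reference ECG peak-to-peak amplitude in mV used to scale EM
#'   events.
#'
#' @return An [ecg_signal]. For `"EM"` the attribute `"events"` holds a data
#'   frame of event start/end times and durations (seconds).
#' @export
generate_noise <- function(kind, duration_s, fs, seed = 1L,
                           em_occupancy = 0.10, em_amp_mult = 2.0,
                           ref_p2p = 1.2) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% NOISE_KINDS)
    stop("unknown noise kind; must be one of ", paste(NOISE_KINDS, collapse = ", "))
  if (duration_s <= 0 || fs <= 0)
    stop("'duration_s' and 'fs' must be positive")
  n <- as.integer(round(duration_s * fs))
  tgrid <- (seq_len(n) - 1L) / fs

  x <- with_seed(seed, switch(
    kind,
    BW = {
      k <- 8L
      f <- stats::runif(k, 0.05, 0.9)
      ph <- stats::runif(k, 0, 2 * pi)
      a <- 1 / sqrt(f)          # redder spectrum at the low end
      v <- colSums(a * sin(outer(f, tgrid, function(fi, ti) 2 * pi * fi * ti) +
                             ph))
      v / max(stats::sd(v), 1e-12)
    },
    EM = {
      mean_dur <- 0.4
      n_ev <- max(1L, as.integer(round(duration_s * em_occupancy / mean_dur)))
      slot <- duration_s / n_ev
      v <- numeric(n)
      starts <- ends <- numeric(n_ev)
      for (e in seq_len(n_ev)) {
        d <- stats::runif(1L, 0.300, 0.500)
        s0 <- (e - 1L) * slot + stats::runif(1L, 0, max(slot - d, 1e-6))
        amp <- em_amp_mult * ref_p2p * sample(c(-1, 1), 1L)
        i0 <- max(1L, as.integer(floor(s0 * fs)) + 1L)
        i1 <- min(n, as.integer(floor((s0 + d) * fs)))
        if (i1 <= i0) next
        m <- i1 - i0 + 1L
        # smooth-edged baseline shift (Tukey-style ramps over 25% each side)
        ramp <- max(2L, as.integer(round(0.25 * m)))
        win <- rep(1, m)
        up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
        win[seq_len(ramp)] <- up
        win[m - ramp + seq_len(ramp)] <- rev(up)
        v[i0:i1] <- v[i0:i1] + amp * win
        starts[e] <- s0; ends[e] <- s0 + d
      }
      keep <- ends > 0
      ev <- data.frame(start = starts[keep], end = ends[keep],
                       duration = ends[keep] - starts[keep])
      # EM keeps its physical amplitude convention (amp_mult x ref_p2p);
      # SNR mixing rescales it when it is blended into a sample.
      structure(v, events = ev)
    },
    MA = {
      ny <- fs / 2
      lo_band <- c(5, min(40, 0.9 * ny)) / ny
      hi_band <- c(min(40, 0.8 * ny), min(95, 0.95 * ny)) / ny
      w1 <- stats::rnorm(n); w2 <- stats::rnorm(n)
      b1 <- signal::butter(4, lo_band, type = "pass")
      v <- signal::filtfilt(b1, w1)
      if (hi_band[2] > hi_band[1] + 1e-3) {
        b2 <- signal::butter(4, hi_band, type = "pass")
        vh <- signal::filtfilt(b2, w2)
        # ~75% of the power in the ECG band, 25% above it
        v <- sqrt(0.75) * v / max(stats::sd(v), 1e-12) +
          sqrt(0.25) * vh / max(stats::sd(vh), 1e-12)
      }
      v <- v - mean(v)
      v / max(stats::sd(v), 1e-12)
    }
  ))

  ev <- attr(x, "events")
  out <- ecg_signal(as.numeric(x), fs)
  if (!is.null(ev)) attr(out, "events") <- ev
  out
}
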