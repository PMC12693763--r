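# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All generators route their randomness through this so
# they are pure functions of their arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# One-sided periodogram: frequencies (Hz) and raw power, no padding/taper.
periodogram <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor(n / 2) + 1L)
  list(freq = (k - 1L) * fs / n, power = p[k])
}

# Fraction of periodogram power in [f_lo, f_hi], excluding DC.
band_power_fraction <- function(x, fs, f_lo, f_hi, f_total = c(0, Inf)) {
  pg <- periodogram(x - mean(x), fs)
  keep <- pg$freq > 0
  fr <- pg$freq[keep]; pw <- pg$power[keep]
  num <- sum(pw[fr >= f_lo & fr <= f_hi])
  den <- sum(pw[fr >= f_total[1] & fr <= f_total[2]])
  if (den <= 0) return(0)
  num / den
}

# Signal power (mean of squares is not used: SNR definitions sum squares).
sumsq <- function(x) sum(x^2)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Odd window length in samples for a window given in seconds.
odd_window <- function(seconds, fs) {
  w <- max(3L, as.integer(round(seconds * fs)))
  if (w %% 2L == 0L) w + 1L else w
}

# Sample entropy (Chebyshev distance, template length m, tolerance r),
# vectorized over the full distance matrix; O(n^2) memory, fine for the
# 1000-2000 sample segments this package works with.
sample_entropy_fast <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2L || !is.finite(r) || r <= 0) return(NA_real_)
  M <- abs(outer(x, x, "-"))
  nm <- n - m
  D <- M[1:nm, 1:nm]
  for (k in seq_len(m - 1L)) D <- pmax(D, M[(1 + k):(nm + k), (1 + k):(nm + k)])
  Dm1 <- pmax(D, M[(1 + m):n, (1 + m):n])
  B <- sum(D < r) - nm    # self-matches excluded
  A <- sum(Dm1 < r) - nm
  if (B <= 0 || A <= 0) return(NA_real_)
  -log(A / B)
}
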