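# Daubechies-6 discrete wavelet transform (periodized, orthogonal filter
# bank) and per-level detail reconstructions. Used for the wavelet
# importance mask of the denoising loss and for ECG delineation.

DB6_DEC_LO <- c(
  -1.0773010853084796e-03, 4.7772575109455108e-03, 5.5384220116149613e-04,
  -3.1582039317486030e-02, 2.7522865530305727e-02, 9.7501605587323043e-02,
  -1.2976686756726194e-01, -2.2626469396543983e-01, 3.1525035170919763e-01,
  7.5113390802109536e-01, 4.9462389039845306e-01, 1.1154074335010947e-01)
# quadrature mirror: h[j] = (-1)^j g[L-1-j] (0-based)
DB6_DEC_HI <- (-1)^(seq_along(DB6_DEC_LO) - 1L) * rev(DB6_DEC_LO)

# One analysis step: y[k] = sum_j f[j] x[(2(k-1)+j-1) mod n + 1].
dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  idx0 <- 2L * (seq_len(half) - 1L)
  y <- numeric(half)
  for (j in seq_along(filt))
    y <- y + filt[j] * x[((idx0 + j - 1L) %% n) + 1L]
  y
}

# Exact transpose of dwt_step for the (lo, hi) pair: perfect reconstruction
# because the periodized analysis map is orthogonal.
idwt_step <- function(a, d) {
  n <- 2L * length(a)
  x <- numeric(n)
  idx0 <- 2L * (seq_along(a) - 1L)
  for (j in seq_along(DB6_DEC_LO)) {
    idx <- ((idx0 + j - 1L) %% n) + 1L
    x[idx] <- x[idx] + DB6_DEC_LO[j] * a + DB6_DEC_HI[j] * d
  }
  x
}

#' Periodized db6 discrete wavelet transform
#'
#' @param x Numeric vector with even length at each level to be split
#'   (odd tails are zero-padded by one sample internally).
#' @param levels Number of decomposition levels (default 4).
#' @return List with `approx` (coarsest approximation), `details` (list of
#'   detail coefficient vectors, element 1 = finest scale), and the original
#'   length `n`.
#' @export
dwt_db6 <- function(x, levels = 4L) {
  a <- as.numeric(x)
  n0 <- length(a)
  pads <- integer(levels)
  details <- vector("list", levels)
  used <- 0L
  for (l in seq_len(levels)) {
    if (length(a) < 2L) break
    if (length(a) %% 2L == 1L) { a <- c(a, 0); pads[l] <- 1L }
    details[[l]] <- dwt_step(a, DB6_DEC_HI)
    a <- dwt_step(a, DB6_DEC_LO)
    used <- l
  }
  list(approx = a, details = details[seq_len(used)],
       pads = pads[seq_len(used)], n = n0)
}

#' Inverse periodized db6 DWT
#' @param w A decomposition from [dwt_db6()].
#' @return Reconstructed numeric vector of the original length.
#' @export
idwt_db6 <- function(w) {
  a <- w$approx
  for (l in rev(seq_along(w$details))) {
    a <- idwt_step(a, w$details[[l]])
    if (w$pads[l] == 1L) a <- a[-length(a)]
  }
  a[seq_len(w$n)]
}

# Time-domain reconstruction of a single detail level (all other
# coefficients zeroed) — maps level-l coefficients back to their support.
dwt_detail_reconstruction <- function(w, level) {
  w2 <- w
  w2$approx <- numeric(length(w$approx))
  for (l in seq_along(w2$details))
    if (l != level) w2$details[[l]] <- numeric(length(w2$details[[l]]))
  idwt_db6(w2)
}
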