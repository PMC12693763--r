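#' Compute the eleven handcrafted signal-quality indices of an ECG segment
#'
#' Features (computed on a preprocessed segment, nominally at 200 Hz):
#' \describe{
#'   \item{f1}{Kurtosis (Pearson, non-excess: white noise is about 3).}
#'   \item{f2}{Sample entropy (m = 2, r = 0.2 x sd).}
#'   \item{f3}{Proportion of crossings of the +-pkThr1 levels, with
#'     pkThr1 = 0.75 x the segment's maximum absolute amplitude.}
#'   \item{f4}{Proportion of samples whose absolute amplitude exceeds
#'     pkThr2 = 0.25 x the maximum absolute amplitude.}
#'   \item{f5}{Proportion of crossings of the +-pkThr2 levels.}
#'   \item{f6}{Band-power ratio 1-40 Hz over the whole band.}
#'   \item{f7}{Band-power ratio 3-20 Hz over 1-40 Hz.}
#'   \item{f8}{Standard deviation of the signal amplitude at the R peaks.}
#'   \item{f9}{Standard deviation of successive RR-interval differences
#'     (in seconds).}
#'   \item{f10}{Average-beat QRS template energy divided by the residual sum
#'     of squares of AASeg, the differences between each P-wave segment and
#'     the average P-wave template.}
#'   \item{f11}{Standard deviation over all P-wave segment samples.}
#' }
#' P-wave segments are the windows \[R - 200 ms, R - 100 ms\]; the QRS
#' template window is \[R - 60 ms, R + 60 ms\]. Features f8-f11 need at
#' least two usable beats and return `NA` (a flagged sentinel) otherwise.
#'
#' @param x An [ecg_signal].
#' @param annotations [beat_annotations]; detected on the fly when `NULL`.
#' @return Named numeric vector `f1` ... `f11`.
#' @export
compute_sqi_features <- function(x, annotations = NULL) {
  stopifnot(inherits(x, "ecg_signal"))
  v <- x$samples
  n <- length(v)
  if (n < 8L) stop("segment too short for SQI features")
  fs <- x$fs
  if (is.null(annotations))
    annotations <- tryCatch(detect_rpeaks(x),
                            error = function(e) beat_annotations(integer(0)))
  r <- annotations$r_peaks + 1L  # 1-based

  m <- mean(v)
  s2 <- mean((v - m)^2)
  f1 <- if (s2 > 0) mean((v - m)^4) / s2^2 else NA_real_

  sdv <- stats::sd(v)
  # cap the O(n^2) entropy computation at 2000 samples (10 s at 200 Hz)
  f2 <- if (sdv > 0)
    sample_entropy_fast(v[seq_len(min(n, 2000L))], m = 2L, r = 0.2 * sdv)
  else NA_real_
  if (!is.finite(f2)) f2 <- NA_real_

  amax <- max(abs(v))
  thr1 <- 0.75 * amax
  thr2 <- 0.25 * amax
  level_crossings <- function(y, thr) {
    if (thr <= 0) return(0)
    c1 <- sum(diff(sign(y - thr)) != 0)
    c2 <- sum(diff(sign(y + thr)) != 0)
    (c1 + c2) / (length(y) - 1L)
  }
  f3 <- level_crossings(v, thr1)
  f4 <- mean(abs(v) > thr2)
  f5 <- level_crossings(v, thr2)

  f6 <- band_power_fraction(v, fs, 1, 40)
  f7 <- band_power_fraction(v, fs, 3, 20, f_total = c(1, 40))

  win <- function(center, lo_s, hi_s) {
    i0 <- center + as.integer(round(lo_s * fs))
    i1 <- center + as.integer(round(hi_s * fs))
    if (i0 < 1L || i1 > n || i1 < i0) return(NULL)
    v[i0:i1]
  }

  if (length(r) >= 2L) {
    f8 <- stats::sd(v[r])
    rr <- diff(r) / fs
    f9 <- if (length(rr) >= 2L) stats::sd(diff(rr)) else NA_real_
    qrs_segs <- Filter(Negate(is.null), lapply(r, win, lo_s = -0.060, hi_s = 0.060))
    p_segs <- Filter(Negate(is.null), lapply(r, win, lo_s = -0.200, hi_s = -0.100))
    f10 <- NA_real_
    f11 <- NA_real_
    if (length(qrs_segs) >= 2L && length(p_segs) >= 2L) {
      qrs_mat <- do.call(cbind, qrs_segs)
      p_mat <- do.call(cbind, p_segs)
      qrs_template <- rowMeans(qrs_mat)
      p_template <- rowMeans(p_mat)
      rss_aaseg <- sum((p_mat - p_template)^2)
      f10 <- if (rss_aaseg > 0) sum(qrs_template^2) / rss_aaseg else Inf
      f11 <- stats::sd(as.vector(p_mat))
    }
  } else {
    f8 <- f9 <- f10 <- f11 <- NA_real_
  }

  c(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5, f6 = f6, f7 = f7,
    f8 = f8, f9 = f9, f10 = f10, f11 = f11)
}

#' Fit a one-class clean-segment selector on reference SQI vectors
#'
#' Standardizes the feature vectors (stored center/scale) and trains a
#' one-class SVM (RBF kernel, `nu = 0.1`, `gamma = 1/(2d)` on the
#' standardized features — the halved width keeps the training-inlier
#' fraction near `1 - nu` on feature sets of this dimension) on segments
#' known to be clean. The fitted selector accepts segments whose SQI vector
#' lies inside the learned support of the clean class.
#'
#' @param features Matrix or data frame of SQI vectors (rows = segments,
#'   11 columns). Rows with non-finite entries are dropped; `Inf` in f10 is
#'   winsorized to the finite column maximum first.
#' @param nu One-class SVM `nu` (expected outlier fraction among the
#'   training data).
#' @param gamma RBF kernel width; default `1/(2 * ncol(features))`.
#' @return A `clean_selector` object.
#' @export
fit_clean_selector <- function(features, nu = 0.1, gamma = NULL) {
  X <- as.matrix(features)
  if (!nrow(X)) stop("empty feature set")
  storage.mode(X) <- "double"
  # winsorize infinities (f10 can be Inf on perfectly repeated beats)
  for (j in seq_len(ncol(X))) {
    inf <- is.infinite(X[, j])
    if (any(inf)) {
      fin <- X[is.finite(X[, j]), j]
      X[inf, j] <- if (length(fin)) max(fin) else 0
    }
  }
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 20L) stop("need at least 20 complete reference vectors")
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Z <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  gamma <- gamma %||% (1 / (2 * ncol(Z)))
  fit <- e1071::svm(Z, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma,
                    scale = FALSE)
  structure(list(svm = fit, center = center, scale = scale, nu = nu,
                 gamma = gamma),
            class = "clean_selector")
}

#' @export
print.clean_selector <- function(x, ...) {
  cat(sprintf("<clean_selector> one-class SVM, nu = %g, %d support vectors\n",
              x$nu, x$svm$tot.nSV))
  invisible(x)
}

#' Apply a clean selector to SQI vectors
#' @param selector A fitted `clean_selector`.
#' @param features Matrix/data frame of SQI vectors.
#' @return Logical vector: accepted (clean) per row; rows with missing
#'   features are rejected.
#' @export
predict_clean <- function(selector, features) {
  stopifnot(inherits(selector, "clean_selector"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  X[is.infinite(X)] <- .Machine$double.xmax / 1e10
  ok <- stats::complete.cases(X)
  out <- logical(nrow(X))
  if (any(ok)) {
    Z <- sweep(sweep(X[ok, , drop = FALSE], 2L, selector$center),
               2L, selector$scale, "/")
    out[ok] <- as.logical(predict(selector$svm, Z))
  }
  out
}

#' Select clean segments from a list of signals
#'
#' Computes SQI features for each segment and returns the indices accepted
#' by the one-class selector. Deterministic given the fitted selector.
#'
#' @param segments List of [ecg_signal]s.
#' @param selector A fitted `clean_selector`.
#' @return Integer vector of accepted indices (possibly empty).
#' @export
select_clean_segments <- function(segments, selector) {
  if (!inherits(selector, "clean_selector"))
    stop("selector is not a fitted clean_selector")
  if (!length(segments)) return(integer(0))
  feats <- t(vapply(segments, function(s) compute_sqi_features(s),
                    numeric(11L)))
  which(predict_clean(selector, feats))
}
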