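#' Wavelet importance mask for the denoising loss
#'
#' Performs a multi-level db6 decomposition of each clean target, hard-
#' thresholds the detail coefficients of the QRS-dominant scales (levels
#' 2-4 at 200 Hz, roughly 3-25 Hz) at the universal threshold
#' `sigma * sqrt(2 log n)` (noise scale `sigma` estimated from the MAD of
#' the finest detail level), and maps the surviving coefficients back to
#' their time support. The resulting binary mask marks the samples whose
#' reconstruction error is amplified for Good-labeled samples, concentrating
#' the denoising objective on diagnostically critical waveform components.
#'
#' @param x_target Matrix (batch x n) of clean reference signals, or a
#'   single numeric vector.
#' @param fs Sampling rate in Hz (default 200).
#' @param levels Decomposition depth (default 4).
#' @param keep_levels Detail levels whose retained coefficients define the
#'   mask (default 2:4).
#' @return Binary matrix of the same shape as `x_target`.
#' @export
wavelet_importance_mask <- function(x_target, fs = 200, levels = 4L,
                                    keep_levels = 2:4) {
  single <- is.null(dim(x_target))
  X <- if (single) matrix(x_target, nrow = 1L) else as.matrix(x_target)
  M <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    v <- X[i, ]
    w <- dwt_db6(v, levels = levels)
    if (!length(w$details)) next
    sigma <- stats::mad(w$details[[1L]])
    thr <- sigma * sqrt(2 * log(length(v)))
    any_alive <- FALSE
    for (l in seq_along(w$details)) {
      d <- w$details[[l]]
      keepc <- (l %in% keep_levels) & (abs(d) > thr)
      w$details[[l]] <- ifelse(keepc, d, 0)
      if (any(keepc)) any_alive <- TRUE
    }
    if (!any_alive) next
    w$approx <- numeric(length(w$approx))
    rec <- idwt_db6(w)
    M[i, ] <- as.numeric(abs(rec) > 1e-10)
  }
  if (single) M[1L, ] else M
}

#' Wavelet-weighted masked denoising loss
#'
#' Pointwise squared reconstruction error, amplified by `alpha` at
#' wavelet-mask positions for Good-labeled samples, averaged over time per
#' sample, then averaged over the non-Bad samples of the batch (Bad samples
#' carry weight 0 — their "clean" reference is meaningless). Returns 0 for
#' an all-Bad batch.
#'
#' @param x_pred,x_target Matrices (batch x n): denoised output and clean
#'   reference.
#' @param y Integer vector of true categories (1 = Good, 2 = Medium,
#'   3 = Bad).
#' @param mask Binary matrix (batch x n) of wavelet importance; computed
#'   from `x_target` when `NULL`.
#' @param alpha Amplification factor for masked points of Good samples
#'   (>= 1; default 2).
#' @param grad Also return the gradient with respect to `x_pred`?
#' @return Scalar loss, or (with `grad = TRUE`) list(loss, grad).
#' @export
denoising_loss <- function(x_pred, x_target, y, mask = NULL, alpha = 2,
                           grad = FALSE) {
  if (alpha < 1) stop("'alpha' must be >= 1")
  x_pred <- as.matrix(x_pred); x_target <- as.matrix(x_target)
  stopifnot(all(dim(x_pred) == dim(x_target)),
            length(y) == nrow(x_pred))
  B <- nrow(x_pred); Tn <- ncol(x_pred)
  ytil <- as.numeric(y != QUALITY_LEVELS[["BAD"]])
  denom <- sum(ytil)
  if (denom == 0) {
    if (grad) return(list(loss = 0, grad = matrix(0, B, Tn)))
    return(0)
  }
  if (is.null(mask)) mask <- wavelet_importance_mask(x_target)
  wts <- matrix(1, B, Tn)
  good <- y == QUALITY_LEVELS[["GOOD"]]
  if (any(good)) wts[good, ] <- 1 + (alpha - 1) * mask[good, , drop = FALSE]
  err <- x_pred - x_target
  per_sample <- rowMeans(wts * err^2)
  loss <- sum(ytil * per_sample) / denom
  if (!grad) return(loss)
  gmat <- (2 * wts * err) * (ytil / (Tn * denom))
  list(loss = loss, grad = gmat)
}

#' Cross-entropy classification loss
#'
#' Mean over the batch of the negative log predicted probability at the true
#' class; probabilities are clamped at 1e-12 so a zero never produces an
#' infinite loss.
#'
#' @param y Integer vector of true categories in 1:3.
#' @param y_hat Matrix (batch x 3) of predicted class probabilities.
#' @param grad Also return the gradient with respect to the logits
#'   (softmax inputs)?
#' @return Scalar loss, or list(loss, grad_logits).
#' @export
classification_loss <- function(y, y_hat, grad = FALSE) {
  y_hat <- as.matrix(y_hat)
  B <- nrow(y_hat)
  stopifnot(length(y) == B, ncol(y_hat) >= max(y))
  p <- pmax(y_hat[cbind(seq_len(B), y)], 1e-12)
  loss <- -mean(log(p))
  if (!grad) return(loss)
  onehot <- matrix(0, B, ncol(y_hat))
  onehot[cbind(seq_len(B), y)] <- 1
  list(loss = loss, grad_logits = (y_hat - onehot) / B)
}

#' Mean-squared-error noise-level loss
#'
#' Mean over batch and time of the squared difference between the predicted
#' noise-level graph and the weak reference labels.
#'
#' @param level_pred,level_ref Matrices (batch x n) with values in \[0,1\].
#' @param grad Also return the gradient with respect to `level_pred`?
#' @return Scalar loss, or list(loss, grad).
#' @export
noise_level_loss <- function(level_pred, level_ref, grad = FALSE) {
  level_pred <- as.matrix(level_pred); level_ref <- as.matrix(level_ref)
  if (!all(dim(level_pred) == dim(level_ref)))
    stop("shape mismatch between prediction and reference")
  d <- level_pred - level_ref
  loss <- mean(d^2)
  if (!grad) return(loss)
  list(loss = loss, grad = 2 * d / length(d))
}

#' Homoscedastic-uncertainty multi-task combination
#'
#' Combines the three task losses as
#' `sum_i L_i / (2 sigma_i^2) + log sigma_i` with `sigma_i =
#' exp(log_sigma_i)`. The task uncertainties are learned jointly with the
#' network: `d/d log_sigma_i = 1 - L_i / sigma_i^2`, so each sigma is pulled
#' toward the scale of its task loss and noisy tasks are down-weighted
#' automatically.
#'
#' @param task_losses Numeric vector of the three task losses.
#' @param log_sigma Numeric vector of log-uncertainties (same length).
#' @param grad Also return gradients (with respect to each task loss, and to
#'   each `log_sigma`)?
#' @return Scalar total loss, or list(loss, d_loss, d_log_sigma).
#' @export
total_loss <- function(task_losses, log_sigma, grad = FALSE) {
  stopifnot(length(task_losses) == length(log_sigma),
            all(is.finite(task_losses)), all(is.finite(log_sigma)))
  s2 <- exp(2 * log_sigma)
  loss <- sum(task_losses / (2 * s2) + log_sigma)
  if (!grad) return(loss)
  list(loss = loss,
       d_loss = 1 / (2 * s2),
       d_log_sigma = 1 - task_losses / s2)
}
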