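#' Classification metrics for three-level quality labels
#'
#' One-vs-rest true/false positives and negatives per class, per-class
#' precision, recall and F1 (zero-division yields 0 with a flag), overall
#' accuracy, support-weighted averages, and the 3x3 confusion matrix.
#'
#' @param y_true,y_pred Integer vectors with labels in 1:3.
#' @return List with `per_class` (data frame), `accuracy`, `weighted`
#'   (named vector), `confusion` (3x3 matrix, rows = true class), and
#'   `zero_division` flag.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (!length(y_true)) stop("empty input")
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% 1:3), all(y_pred %in% 1:3))
  cm <- matrix(0L, 3L, 3L,
               dimnames = list(true = c("Good", "Medium", "Bad"),
                               pred = c("Good", "Medium", "Bad")))
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  zero_div <- FALSE
  per <- lapply(1:3, function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    prec <- if (tp + fp == 0) { zero_div <<- TRUE; 0 } else tp / (tp + fp)
    rec <- if (tp + fn == 0) { zero_div <<- TRUE; 0 } else tp / (tp + fn)
    f1 <- if (prec + rec == 0) { zero_div <<- TRUE; 0 } else
      2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1, support = tp + fn)
  })
  per_class <- as.data.frame(do.call(rbind, per))
  rownames(per_class) <- c("Good", "Medium", "Bad")
  support <- per_class$support
  wavg <- function(v) if (sum(support) > 0) sum(v * support) / sum(support) else 0
  list(per_class = per_class,
       accuracy = sum(diag(cm)) / length(y_true),
       weighted = c(precision = wavg(per_class$precision),
                    recall = wavg(per_class$recall),
                    f1 = wavg(per_class$f1)),
       confusion = cm,
       zero_division = zero_div)
}

#' Denoising metrics between a clean reference and a reconstruction
#'
#' * PRD: percentage root-mean-square difference,
#'   `100 * sqrt(sum((x - xhat)^2) / sum(x^2))`.
#' * RMSE: root of the mean squared error (mV).
#' * SNR: `10 * log10(sum(x^2) / sum((x - xhat)^2))` dB; `Inf` (flagged)
#'   when the reconstruction is exact.
#' * CosSim: cosine similarity `sum(x * xhat) / sqrt(sum(x^2) sum(xhat^2))`
#'   (positive-sign convention).
#'
#' @param x Clean reference (numeric vector or [ecg_signal]).
#' @param x_hat Reconstruction of the same length.
#' @return Named list `prd`, `rmse`, `snr_db`, `cossim`, `exact` (logical
#'   flag set when `x_hat == x` so the infinite SNR can be excluded from
#'   averages).
#' @export
denoising_metrics <- function(x, x_hat) {
  if (inherits(x, "ecg_signal")) x <- x$samples
  if (inherits(x_hat, "ecg_signal")) x_hat <- x_hat$samples
  stopifnot(length(x) == length(x_hat))
  px <- sumsq(x)
  if (px <= 0) stop("clean reference has zero power")
  res <- sumsq(x - x_hat)
  exact <- res == 0
  list(prd = 100 * sqrt(res / px),
       rmse = sqrt(res / length(x)),
       snr_db = if (exact) Inf else 10 * log10(px / res),
       cossim = sum(x * x_hat) / sqrt(px * sumsq(x_hat)),
       exact = exact)
}
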