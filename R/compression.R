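# Model compression: structured pruning of conv channels, attention heads
# and FFN hidden units, then 8-bit post-training weight quantization.

#' Structured pruning of conv channels, attention heads and FFN units
#'
#' Ranks whole structures — embedding-conv output channels, per-block
#' attention heads, per-block FFN hidden units — by importance (mean
#' absolute weight over the structure, the L1 magnitude criterion) and
#' removes the least important until the trainable-parameter count drops to
#' `(1 - target_reduction)` of the original. Adjacent layers are rewired so
#' every forward shape stays valid; the model's input/output contract
#' (1000 samples in, 1000/1000/3 out) is unchanged. At least `min_channels`
#' conv channels, one attention head and `min_ffn` FFN units per block are
#' kept; if the target cannot be reached within those floors an error
#' reports the achievable reduction.
#'
#' @param model An `ecg_model`.
#' @param target_reduction Fraction of parameters to remove, in (0, 1);
#'   default 0.80.
#' @param min_channels,min_ffn Structural floors.
#' @return List with `model` (pruned `ecg_model`, its `config` updated) and
#'   `removed` (data frame log of removed structures, in removal order).
#' @export
prune_structured <- function(model, target_reduction = 0.80,
                             min_channels = 4L, min_ffn = 4L) {
  if (!is.numeric(target_reduction) || target_reduction <= 0 ||
      target_reduction >= 1)
    stop("'target_reduction' must be in the open interval (0, 1)")
  cfg <- model$config
  p <- model$params
  orig <- count_parameters(cfg)$total
  target <- (1 - target_reduction) * orig

  # ---- enumerate prunable structures with static L1 importance ----------
  cand <- list()
  add <- function(kind, block, idx, imp)
    cand[[length(cand) + 1L]] <<- list(kind = kind, block = block,
                                       idx = idx, imp = imp)
  for (ch in seq_len(cfg$embed_channels[1L]))
    add("conv1_ch", NA_integer_, ch,
        mean(abs(c(p$embed$conv1$W[, , ch], p$embed$conv2$W[, ch, ]))))
  for (ch in seq_len(cfg$embed_channels[2L]))
    add("conv2_ch", NA_integer_, ch,
        mean(abs(c(p$embed$conv2$W[, , ch], p$embed$conv3$W[, ch, ]))))
  enum_blocks <- function(blocks, heads, head_dim, side) {
    for (b in seq_along(blocks)) {
      at <- blocks[[b]]$attn
      for (h in seq_len(heads[b])) {
        cols <- ((h - 1L) * head_dim + 1L):(h * head_dim)
        add(paste0(side, "_head"), b, h,
            mean(abs(c(at$Wq[, cols], at$Wk[, cols], at$Wv[, cols],
                       at$Wo[cols, ]))))
      }
      fw <- blocks[[b]]$ffn
      imps <- (colSums(abs(fw$W1)) + rowSums(abs(fw$W2))) /
        (nrow(fw$W1) + ncol(fw$W2))
      for (u in seq_along(imps))
        add(paste0(side, "_ffn"), b, u, imps[u])
    }
  }
  enum_blocks(p$enc_blocks, cfg$enc_heads, cfg$head_dim_enc, "enc")
  enum_blocks(p$dec_blocks, cfg$dec_heads, cfg$head_dim_dec, "dec")
  cand <- cand[order(vapply(cand, `[[`, 0, "imp"))]

  # ---- plan removals on keep-masks, tracking the parameter count --------
  keep <- list(
    conv1 = rep(TRUE, cfg$embed_channels[1L]),
    conv2 = rep(TRUE, cfg$embed_channels[2L]),
    enc_head = lapply(cfg$enc_heads, function(h) rep(TRUE, h)),
    dec_head = lapply(cfg$dec_heads, function(h) rep(TRUE, h)),
    enc_ffn = lapply(cfg$enc_ffn_hidden, function(u) rep(TRUE, u)),
    dec_ffn = lapply(cfg$dec_ffn_hidden, function(u) rep(TRUE, u))
  )
  cfg2 <- cfg
  removed <- list()
  reached <- count_parameters(cfg2)$total <= target
  for (cd in cand) {
    if (reached) break
    ok <- switch(cd$kind,
      conv1_ch = cfg2$embed_channels[1L] > min_channels,
      conv2_ch = cfg2$embed_channels[2L] > min_channels,
      enc_head = cfg2$enc_heads[cd$block] > 1L,
      dec_head = cfg2$dec_heads[cd$block] > 1L,
      enc_ffn = cfg2$enc_ffn_hidden[cd$block] > min_ffn,
      dec_ffn = cfg2$dec_ffn_hidden[cd$block] > min_ffn)
    if (!ok) next
    switch(cd$kind,
      conv1_ch = { keep$conv1[cd$idx] <- FALSE
        cfg2$embed_channels[1L] <- cfg2$embed_channels[1L] - 1L },
      conv2_ch = { keep$conv2[cd$idx] <- FALSE
        cfg2$embed_channels[2L] <- cfg2$embed_channels[2L] - 1L },
      enc_head = { keep$enc_head[[cd$block]][cd$idx] <- FALSE
        cfg2$enc_heads[cd$block] <- cfg2$enc_heads[cd$block] - 1L },
      dec_head = { keep$dec_head[[cd$block]][cd$idx] <- FALSE
        cfg2$dec_heads[cd$block] <- cfg2$dec_heads[cd$block] - 1L },
      enc_ffn = { keep$enc_ffn[[cd$block]][cd$idx] <- FALSE
        cfg2$enc_ffn_hidden[cd$block] <- cfg2$enc_ffn_hidden[cd$block] - 1L },
      dec_ffn = { keep$dec_ffn[[cd$block]][cd$idx] <- FALSE
        cfg2$dec_ffn_hidden[cd$block] <- cfg2$dec_ffn_hidden[cd$block] - 1L })
    removed[[length(removed) + 1L]] <-
      data.frame(kind = cd$kind, block = cd$block, index = cd$idx,
                 importance = cd$imp)
    reached <- count_parameters(cfg2)$total <= target
  }
  if (!reached) {
    ach <- 1 - count_parameters(cfg2)$total / orig
    stop(sprintf(paste0("requested reduction %.2f infeasible at this ",
                        "granularity; achievable at most %.3f"),
                 target_reduction, ach))
  }

  # ---- apply the masks: slice parameters and rewire neighbours ----------
  kc1 <- which(keep$conv1); kc2 <- which(keep$conv2)
  p$embed$conv1$W <- p$embed$conv1$W[, , kc1, drop = FALSE]
  p$embed$conv1$b <- p$embed$conv1$b[kc1]
  p$embed$bn1$gamma <- p$embed$bn1$gamma[kc1]
  p$embed$bn1$beta <- p$embed$bn1$beta[kc1]
  model$state$bn1$mean <- model$state$bn1$mean[kc1]
  model$state$bn1$var <- model$state$bn1$var[kc1]
  p$embed$conv2$W <- p$embed$conv2$W[, kc1, kc2, drop = FALSE]
  p$embed$conv2$b <- p$embed$conv2$b[kc2]
  p$embed$bn2$gamma <- p$embed$bn2$gamma[kc2]
  p$embed$bn2$beta <- p$embed$bn2$beta[kc2]
  model$state$bn2$mean <- model$state$bn2$mean[kc2]
  model$state$bn2$var <- model$state$bn2$var[kc2]
  p$embed$conv3$W <- p$embed$conv3$W[, kc2, , drop = FALSE]

  slice_blocks <- function(blocks, keep_heads, keep_ffn, head_dim) {
    for (b in seq_along(blocks)) {
      kh <- keep_heads[[b]]
      cols <- as.vector(outer(seq_len(head_dim), which(kh) - 1L,
                              function(j, h) h * head_dim + j))
      at <- blocks[[b]]$attn
      at$Wq <- at$Wq[, cols, drop = FALSE]; at$bq <- at$bq[cols]
      at$Wk <- at$Wk[, cols, drop = FALSE]; at$bk <- at$bk[cols]
      at$Wv <- at$Wv[, cols, drop = FALSE]; at$bv <- at$bv[cols]
      at$Wo <- at$Wo[cols, , drop = FALSE]
      at$n_heads <- sum(kh)
      blocks[[b]]$attn <- at
      ku <- which(keep_ffn[[b]])
      blocks[[b]]$ffn$W1 <- blocks[[b]]$ffn$W1[, ku, drop = FALSE]
      blocks[[b]]$ffn$b1 <- blocks[[b]]$ffn$b1[ku]
      blocks[[b]]$ffn$W2 <- blocks[[b]]$ffn$W2[ku, , drop = FALSE]
    }
    blocks
  }
  p$enc_blocks <- slice_blocks(p$enc_blocks, keep$enc_head, keep$enc_ffn,
                               cfg$head_dim_enc)
  p$dec_blocks <- slice_blocks(p$dec_blocks, keep$dec_head, keep$dec_ffn,
                               cfg$head_dim_dec)

  model$params <- p
  model$config <- cfg2
  stopifnot(n_scalars(model$params) == count_parameters(cfg2)$total)
  list(model = model,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame())
}

#' Post-training 8-bit weight quantization
#'
#' Maps every weight tensor to 8-bit integers with a per-tensor affine
#' scale/zero-point; the elementwise dequantization error is at most half
#' the scale. Parameter count is unchanged. Inference runs on the
#' dequantized weights via [dequantize_model()].
#'
#' @param model An `ecg_model`.
#' @return A `quantized_model`: list with `config`, `state`, and `tensors`
#'   (per-tensor integer values, scale, zero point, dims).
#' @export
quantize_int8 <- function(model) {
  pf <- flatten_params(model$params)
  tensors <- lapply(pf, function(w) {
    wv <- as.numeric(w)
    if (!all(is.finite(wv))) stop("weights must be finite")
    lo <- min(wv); hi <- max(wv)
    if (hi == lo) {
      if (lo == 0) { scale <- 1; q <- rep(0L, length(wv)) }
      else { scale <- lo; q <- rep(1L, length(wv)) }
      zp <- 0L
    } else {
      scale <- (hi - lo) / 255
      zp <- as.integer(round(-128 - lo / scale))
      q <- as.integer(pmin(pmax(round(wv / scale) + zp, -128L), 127L))
    }
    list(q = q, scale = scale, zp = zp, dims = dim(w) %||% length(w))
  })
  structure(list(config = model$config, state = model$state,
                 tensors = tensors),
            class = "quantized_model")
}

#' Reconstruct a runnable model from a quantized state
#' @param qm A `quantized_model` from [quantize_int8()].
#' @return An `ecg_model` with dequantized weights.
#' @export
dequantize_model <- function(qm) {
  stopifnot(inherits(qm, "quantized_model"))
  model <- build_model(qm$config, seed = 1L)
  model$state <- qm$state
  for (nm in names(qm$tensors)) {
    tz <- qm$tensors[[nm]]
    w <- (tz$q - tz$zp) * tz$scale
    if (length(tz$dims) > 1L) dim(w) <- tz$dims
    model$params <- set_by_path(model$params, nm, w)
  }
  model
}

#' Storage accounting for a model state
#'
#' fp32 stores 4 bytes per parameter; int8 stores 1 byte per parameter plus
#' a scale and zero point (two 4-byte values) per tensor.
#'
#' @param model An `ecg_model` or `quantized_model`.
#' @param precision `"fp32"` or `"int8"`.
#' @return List with `params`, `bytes`, `mib` (2^20 bytes).
#' @export
storage_bytes <- function(model, precision = c("fp32", "int8")) {
  precision <- match.arg(precision)
  if (inherits(model, "quantized_model")) {
    n <- sum(vapply(model$tensors, function(t) length(t$q), 0L))
    n_tensors <- length(model$tensors)
  } else {
    pf <- flatten_params(model$params)
    n <- sum(vapply(pf, length, 0L))
    n_tensors <- length(pf)
  }
  bytes <- if (precision == "fp32") 4 * n else n + 8 * n_tensors
  list(params = n, bytes = bytes, mib = bytes / 2^20)
}
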