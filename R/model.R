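#' Model configuration for the multi-task ECG network
#'
#' Describes the conv patch embedding (three 1-D convolutions), the
#' positional-encoding-free Transformer encoder and decoder, and the three
#' prediction heads. Per-block head counts and FFN widths are vectors so a
#' structurally pruned model is described by the same object.
#'
#' @param input_len Input window length in samples (default 1000 = 5 s at
#'   200 Hz).
#' @param patch_size Patch length in samples (default 20); the stride is
#'   half the patch size.
#' @param embed_channels Channels of the first two embedding convolutions.
#' @param embed_kernels Kernel sizes of the first two embedding convolutions.
#' @param d_model_enc,d_model_dec Encoder/decoder model widths.
#' @param enc_blocks,dec_blocks Numbers of Transformer blocks.
#' @param heads Attention heads per block (scalar, applied to all blocks; or
#'   per-block integer vectors via `enc_heads`/`dec_heads`).
#' @param enc_heads,dec_heads Optional per-block head counts.
#' @param mlp_ratio FFN hidden width as a multiple of the model width
#'   (scalar; or per-block widths via `enc_ffn_hidden`/`dec_ffn_hidden`).
#' @param enc_ffn_hidden,dec_ffn_hidden Optional per-block FFN widths.
#' @param n_classes Number of quality classes (3).
#' @param dropout Dropout rate in the classification head.
#' @param smooth_kernel Kernel size of the output smoothing convolution.
#' @return A `model_config` object.
#' @export
model_config <- function(input_len = 1000L, patch_size = 20L,
                         embed_channels = c(32L, 64L),
                         embed_kernels = c(15L, 7L),
                         d_model_enc = 128L, d_model_dec = 64L,
                         enc_blocks = 6L, dec_blocks = 3L, heads = 8L,
                         enc_heads = NULL, dec_heads = NULL,
                         mlp_ratio = 3, enc_ffn_hidden = NULL,
                         dec_ffn_hidden = NULL, n_classes = 3L,
                         dropout = 0.1, smooth_kernel = 5L,
                         head_dim_enc = NULL, head_dim_dec = NULL) {
  stride <- patch_size %/% 2L
  if (input_len %% stride != 0L)
    stop("input_len must be a multiple of patch_size/2")
  derive_enc <- is.null(enc_heads)
  derive_dec <- is.null(dec_heads)
  enc_heads <- enc_heads %||% rep(as.integer(heads), enc_blocks)
  dec_heads <- dec_heads %||% rep(as.integer(heads), dec_blocks)
  max0 <- function(v) if (length(v)) max(v) else 1L
  head_dim_enc <- head_dim_enc %||% (d_model_enc %/% max0(enc_heads))
  head_dim_dec <- head_dim_dec %||% (d_model_dec %/% max0(dec_heads))
  if (derive_enc && length(enc_heads) &&
      head_dim_enc * max(enc_heads) != d_model_enc)
    stop("encoder d_model not divisible by heads")
  if (derive_dec && length(dec_heads) &&
      head_dim_dec * max(dec_heads) != d_model_dec)
    stop("decoder d_model not divisible by heads")
  enc_ffn_hidden <- enc_ffn_hidden %||% rep(as.integer(round(mlp_ratio * d_model_enc)), enc_blocks)
  dec_ffn_hidden <- dec_ffn_hidden %||% rep(as.integer(round(mlp_ratio * d_model_dec)), dec_blocks)
  structure(list(
    input_len = as.integer(input_len), patch_size = as.integer(patch_size),
    patch_stride = stride, n_patches = as.integer(input_len %/% stride),
    embed_channels = as.integer(embed_channels),
    embed_kernels = as.integer(embed_kernels),
    d_model_enc = as.integer(d_model_enc), d_model_dec = as.integer(d_model_dec),
    enc_blocks = as.integer(enc_blocks), dec_blocks = as.integer(dec_blocks),
    enc_heads = as.integer(enc_heads), dec_heads = as.integer(dec_heads),
    head_dim_enc = as.integer(head_dim_enc), head_dim_dec = as.integer(head_dim_dec),
    enc_ffn_hidden = as.integer(enc_ffn_hidden),
    dec_ffn_hidden = as.integer(dec_ffn_hidden),
    n_classes = as.integer(n_classes), dropout = dropout,
    smooth_kernel = as.integer(smooth_kernel)
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> in %d, %d patches x %d | enc %d blocks @ %d | dec %d blocks @ %d | %d classes\n",
              x$input_len, x$n_patches, x$d_model_enc, x$enc_blocks,
              x$d_model_enc, x$dec_blocks, x$d_model_dec, x$n_classes))
  invisible(x)
}

#' Closed-form trainable-parameter accounting per stage
#'
#' Counts trainable scalars (conv weights and biases, normalization affine
#' pairs, attention projections with biases, FFN weights and biases, head
#' linears) without instantiating the network; matches an instantiated
#' model's count exactly.
#'
#' @param config A [model_config()].
#' @return Named list with `patch_embed`, `encoder`, `decoder`, `heads`,
#'   `total` (integer scalar counts).
#' @export
count_parameters <- function(config) {
  cfg <- config
  c1 <- cfg$embed_channels[1L]; c2 <- cfg$embed_channels[2L]
  k1 <- cfg$embed_kernels[1L]; k2 <- cfg$embed_kernels[2L]
  de <- cfg$d_model_enc; dd <- cfg$d_model_dec
  embed <- (k1 * 1L * c1 + c1) + 2L * c1 +
    (k2 * c1 * c2 + c2) + 2L * c2 +
    (cfg$patch_size * c2 * de + de) + 2L * de
  block_count <- function(d, n_heads, head_dim, fh) {
    dh <- n_heads * head_dim
    attn <- 3L * (d * dh + dh) + (dh * d + d)
    ffn <- d * fh + fh + fh * d + d
    norms <- 4L * d
    attn + ffn + norms
  }
  encoder <- sum(vapply(seq_len(cfg$enc_blocks), function(b)
    block_count(de, cfg$enc_heads[b], cfg$head_dim_enc, cfg$enc_ffn_hidden[b]), 0L))
  decoder <- (de * dd + dd) + sum(vapply(seq_len(cfg$dec_blocks), function(b)
    block_count(dd, cfg$dec_heads[b], cfg$head_dim_dec, cfg$dec_ffn_hidden[b]), 0L))
  heads <- (dd * cfg$patch_size + cfg$patch_size) +      # denoising linear
    (cfg$smooth_kernel + 1L) +                           # smoothing conv
    (dd * cfg$patch_size + cfg$patch_size) +             # noise-level linear
    (dd * cfg$n_classes + cfg$n_classes)                 # classification
  list(patch_embed = embed, encoder = encoder, decoder = decoder,
       heads = heads, total = embed + encoder + decoder + heads)
}

#' Instantiate the multi-task ECG model
#'
#' Builds all trainable parameters with Xavier (uniform variance-scaling)
#' initialization and zero biases; normalization scales start at 1.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initialization draw.
#' @return An `ecg_model`: list with `config`, `params` (nested parameter
#'   arrays) and `state` (batch-norm running statistics).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  cfg <- config
  c1 <- cfg$embed_channels[1L]; c2 <- cfg$embed_channels[2L]
  k1 <- cfg$embed_kernels[1L]; k2 <- cfg$embed_kernels[2L]
  de <- cfg$d_model_enc; dd <- cfg$d_model_dec; ps <- cfg$patch_size
  params <- with_seed(seed, list(
    embed = list(
      conv1 = list(W = xavier_init(k1 * 1L, k1 * c1, c(k1, 1L, c1)), b = rep(0, c1)),
      bn1 = list(gamma = rep(1, c1), beta = rep(0, c1)),
      conv2 = list(W = xavier_init(k2 * c1, k2 * c2, c(k2, c1, c2)), b = rep(0, c2)),
      bn2 = list(gamma = rep(1, c2), beta = rep(0, c2)),
      conv3 = list(W = xavier_init(ps * c2, ps * de, c(ps, c2, de)), b = rep(0, de)),
      ln = list(gamma = rep(1, de), beta = rep(0, de))
    ),
    enc_blocks = lapply(seq_len(cfg$enc_blocks), function(b)
      init_block(de, cfg$enc_heads[b], cfg$head_dim_enc, cfg$enc_ffn_hidden[b])),
    dec_proj = list(W = xavier_init(de, dd, c(de, dd)), b = rep(0, dd)),
    dec_blocks = lapply(seq_len(cfg$dec_blocks), function(b)
      init_block(dd, cfg$dec_heads[b], cfg$head_dim_dec, cfg$dec_ffn_hidden[b])),
    heads = list(
      den_lin = list(W = xavier_init(dd, ps, c(dd, ps)), b = rep(0, ps)),
      smooth = list(W = array(c(rep(0, cfg$smooth_kernel %/% 2L), 1,
                                rep(0, cfg$smooth_kernel - 1L - cfg$smooth_kernel %/% 2L)),
                              dim = c(cfg$smooth_kernel, 1L, 1L)),
                    b = 0),
      lvl_lin = list(W = xavier_init(dd, ps, c(dd, ps)), b = rep(0, ps)),
      cls_lin = list(W = xavier_init(dd, cfg$n_classes, c(dd, cfg$n_classes)),
                     b = rep(0, cfg$n_classes))
    )
  ))
  state <- list(
    bn1 = list(mean = rep(0, c1), var = rep(1, c1)),
    bn2 = list(mean = rep(0, c2), var = rep(1, c2))
  )
  structure(list(config = cfg, params = params, state = state),
            class = "ecg_model")
}

#' @export
print.ecg_model <- function(x, ...) {
  ct <- count_parameters(x$config)
  cat(sprintf("<ecg_model> %s total trainable parameters (%.3f M)\n",
              format(ct$total, big.mark = ","), ct$total / 1e6))
  print(x$config)
  invisible(x)
}

# index map for (un)patchify: sample position of element j of patch p
patch_positions <- function(cfg) {
  pad <- (cfg$patch_size - cfg$patch_stride) %/% 2L
  outer(seq_len(cfg$n_patches) - 1L, seq_len(cfg$patch_size),
        function(p, j) p * cfg$patch_stride - pad + j)  # 1-based, may exceed
}

#' Cut a batch of signals into overlapping patches
#' @param X Matrix (batch x input_len).
#' @param config A [model_config()].
#' @return Array (batch, n_patches, patch_size); out-of-range positions are
#'   zero-padded.
#' @export
patchify <- function(X, config = model_config()) {
  B <- nrow(X); n <- config$input_len
  stopifnot(ncol(X) == n)
  pos <- patch_positions(config)
  P <- array(0, dim = c(B, config$n_patches, config$patch_size))
  for (j in seq_len(config$patch_size)) {
    pj <- pos[, j]
    ok <- pj >= 1L & pj <= n
    P[, ok, j] <- X[, pj[ok]]
  }
  P
}

#' Overlap-add reconstruction from overlapping patches
#'
#' Inverse of [patchify()]: each sample is the average of all patch values
#' covering it (positions covered once keep their single value).
#'
#' @param P Array (batch, n_patches, patch_size).
#' @param config A [model_config()].
#' @return Matrix (batch x input_len).
#' @export
unpatchify <- function(P, config = model_config()) {
  B <- dim(P)[1L]; n <- config$input_len
  pos <- patch_positions(config)
  Y <- matrix(0, B, n)
  cnt <- numeric(n)
  for (j in seq_len(config$patch_size)) {
    pj <- pos[, j]
    ok <- which(pj >= 1L & pj <= n)
    tt <- pj[ok]
    Y[, tt] <- Y[, tt] + P[, ok, j]
    cnt[tt] <- cnt[tt] + 1L
  }
  sweep(Y, 2L, pmax(cnt, 1), "/")
}

unpatchify_backward <- function(dY, config) {
  B <- nrow(dY); n <- config$input_len
  pos <- patch_positions(config)
  cnt <- numeric(n)
  for (j in seq_len(config$patch_size)) {
    pj <- pos[, j]; ok <- pj >= 1L & pj <= n
    cnt[pj[ok]] <- cnt[pj[ok]] + 1L
  }
  dYs <- sweep(dY, 2L, pmax(cnt, 1), "/")
  dP <- array(0, dim = c(B, config$n_patches, config$patch_size))
  for (j in seq_len(config$patch_size)) {
    pj <- pos[, j]
    ok <- which(pj >= 1L & pj <= n)
    dP[, ok, j] <- dYs[, pj[ok]]
  }
  dP
}

#' Forward pass of the multi-task model
#'
#' @param model An `ecg_model`.
#' @param X Matrix (batch x input_len) of ECG windows (mV).
#' @param training Logical; enables batch statistics, dropout, and cache
#'   collection for backpropagation. Evaluation mode is deterministic.
#' @param dropout_seed Seed for the dropout mask when training.
#' @return List with `denoised` (B x n), `noise_level` (B x n, in \[0,1\]),
#'   `class_probs` (B x 3, rows sum to 1), `logits`, `tokens_enc`,
#'   `tokens_dec`, and (when training) `cache`.
#' @export
model_forward <- function(model, X, training = FALSE, dropout_seed = NULL) {
  cfg <- model$config; p <- model$params
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  B <- nrow(X)
  if (ncol(X) != cfg$input_len) stop("input length must be ", cfg$input_len)
  X3 <- array(X, dim = c(B, cfg$input_len, 1L))

  cv1 <- conv1d_forward(X3, p$embed$conv1$W, p$embed$conv1$b)
  bn1 <- batchnorm_forward(cv1$out, p$embed$bn1$gamma, p$embed$bn1$beta,
                           model$state$bn1, training)
  r1 <- relu_forward(bn1$out)
  cv2 <- conv1d_forward(r1$out, p$embed$conv2$W, p$embed$conv2$b)
  bn2 <- batchnorm_forward(cv2$out, p$embed$bn2$gamma, p$embed$bn2$beta,
                           model$state$bn2, training)
  r2 <- relu_forward(bn2$out)
  pad3 <- (cfg$patch_size - cfg$patch_stride) %/% 2L
  cv3 <- conv1d_forward(r2$out, p$embed$conv3$W, p$embed$conv3$b,
                        stride = cfg$patch_stride, pad = c(pad3, pad3))
  ln3 <- layernorm_forward(cv3$out, p$embed$ln$gamma, p$embed$ln$beta)
  r3 <- relu_forward(ln3$out)

  tok <- r3$out
  enc_caches <- vector("list", cfg$enc_blocks)
  for (bk in seq_len(cfg$enc_blocks)) {
    bf <- block_forward(tok, p$enc_blocks[[bk]])
    tok <- bf$out; enc_caches[[bk]] <- bf$cache
  }
  tokens_enc <- tok

  pj <- linear_forward(tok, p$dec_proj$W, p$dec_proj$b)
  tok <- pj$out
  dec_caches <- vector("list", cfg$dec_blocks)
  for (bk in seq_len(cfg$dec_blocks)) {
    bf <- block_forward(tok, p$dec_blocks[[bk]])
    tok <- bf$out; dec_caches[[bk]] <- bf$cache
  }
  tokens_dec <- tok

  den_l <- linear_forward(tok, p$heads$den_lin$W, p$heads$den_lin$b)
  den_up <- unpatchify(array(den_l$out, dim = dim(den_l$out)), cfg)
  den_arr <- array(den_up, dim = c(B, cfg$input_len, 1L))
  sm <- conv1d_forward(den_arr, p$heads$smooth$W, p$heads$smooth$b)
  denoised <- matrix(sm$out, B, cfg$input_len)

  lvl_l <- linear_forward(tok, p$heads$lvl_lin$W, p$heads$lvl_lin$b)
  lvl_up <- unpatchify(lvl_l$out, cfg)
  noise_level <- 1 / (1 + exp(-lvl_up))

  gap <- matrix(0, B, cfg$d_model_dec)
  for (cidx in seq_len(cfg$d_model_dec)) gap[, cidx] <- rowMeans(tok[, , cidx, drop = FALSE])
  drop_mask <- NULL
  gap_d <- gap
  if (training && cfg$dropout > 0) {
    drop_mask <- with_seed(dropout_seed %||% 1L,
                           matrix(stats::runif(length(gap)) >= cfg$dropout,
                                  nrow(gap), ncol(gap)))
    gap_d <- gap * drop_mask / (1 - cfg$dropout)
  }
  cls <- linear_forward(gap_d, p$heads$cls_lin$W, p$heads$cls_lin$b)
  logits <- cls$out
  probs <- row_softmax(logits)

  out <- list(denoised = denoised, noise_level = noise_level,
              class_probs = probs, logits = logits,
              tokens_enc = tokens_enc, tokens_dec = tokens_dec)
  if (training) {
    out$cache <- list(cv1 = cv1, bn1 = bn1, r1 = r1, cv2 = cv2, bn2 = bn2,
                      r2 = r2, cv3 = cv3, ln3 = ln3, r3 = r3,
                      enc = enc_caches, proj = pj, dec = dec_caches,
                      den_l = den_l, sm = sm, lvl_l = lvl_l,
                      noise_level = noise_level, drop_mask = drop_mask,
                      gap = gap, cls = cls, B = B)
    out$state <- list(bn1 = bn1$running, bn2 = bn2$running)
  }
  out
}

# Backward pass: gradients of a scalar loss wrt all trainable parameters.
# d_denoised, d_level: (B x n) gradients at the (post-activation) outputs;
# d_logits: (B x 3) gradient at the classification logits.
model_backward <- function(model, cache, d_denoised, d_level, d_logits) {
  cfg <- model$config; p <- model$params
  B <- cache$B
  g <- list()

  # classification head
  clb <- linear_backward(d_logits, cache$cls$cache)
  g$heads$cls_lin <- list(W = clb$dW, b = clb$db)
  dgap <- clb$dX
  if (!is.null(cache$drop_mask))
    dgap <- dgap * cache$drop_mask / (1 - cfg$dropout)
  dtok_cls <- array(0, dim = c(B, cfg$n_patches, cfg$d_model_dec))
  for (cidx in seq_len(cfg$d_model_dec))
    dtok_cls[, , cidx] <- matrix(dgap[, cidx], B, cfg$n_patches) / cfg$n_patches

  # noise-level head (through the sigmoid)
  s <- cache$noise_level
  dpre <- d_level * s * (1 - s)
  dlvl_p <- unpatchify_backward(dpre, cfg)
  lvb <- linear_backward(dlvl_p, cache$lvl_l$cache)
  g$heads$lvl_lin <- list(W = lvb$dW, b = lvb$db)

  # denoising head (through the smoothing conv and overlap-add)
  dden_arr <- array(d_denoised, dim = c(B, cfg$input_len, 1L))
  smb <- conv1d_backward(dden_arr, cache$sm$cache)
  g$heads$smooth <- list(W = smb$dW, b = smb$db)
  dden_up <- matrix(smb$dX, B, cfg$input_len)
  dden_p <- unpatchify_backward(dden_up, cfg)
  dnb <- linear_backward(dden_p, cache$den_l$cache)
  g$heads$den_lin <- list(W = dnb$dW, b = dnb$db)

  dtok <- lvb$dX + dnb$dX + dtok_cls

  g$dec_blocks <- vector("list", cfg$dec_blocks)
  for (bk in rev(seq_len(cfg$dec_blocks))) {
    bb <- block_backward(dtok, cache$dec[[bk]], p$dec_blocks[[bk]])
    g$dec_blocks[[bk]] <- bb$grads
    dtok <- bb$dX
  }
  pjb <- linear_backward(dtok, cache$proj$cache)
  g$dec_proj <- list(W = pjb$dW, b = pjb$db)
  dtok <- pjb$dX

  g$enc_blocks <- vector("list", cfg$enc_blocks)
  for (bk in rev(seq_len(cfg$enc_blocks))) {
    bb <- block_backward(dtok, cache$enc[[bk]], p$enc_blocks[[bk]])
    g$enc_blocks[[bk]] <- bb$grads
    dtok <- bb$dX
  }

  dr3 <- relu_backward(dtok, cache$r3$cache)
  ln3b <- layernorm_backward(dr3, cache$ln3$cache)
  g$embed$ln <- list(gamma = ln3b$dgamma, beta = ln3b$dbeta)
  cv3b <- conv1d_backward(ln3b$dX, cache$cv3$cache)
  g$embed$conv3 <- list(W = cv3b$dW, b = cv3b$db)
  dr2 <- relu_backward(cv3b$dX, cache$r2$cache)
  bn2b <- batchnorm_backward(dr2, cache$bn2$cache)
  g$embed$bn2 <- list(gamma = bn2b$dgamma, beta = bn2b$dbeta)
  cv2b <- conv1d_backward(bn2b$dX, cache$cv2$cache)
  g$embed$conv2 <- list(W = cv2b$dW, b = cv2b$db)
  dr1 <- relu_backward(cv2b$dX, cache$r1$cache)
  bn1b <- batchnorm_backward(dr1, cache$bn1$cache)
  g$embed$bn1 <- list(gamma = bn1b$dgamma, beta = bn1b$dbeta)
  cv1b <- conv1d_backward(bn1b$dX, cache$cv1$cache)
  g$embed$conv1 <- list(W = cv1b$dW, b = cv1b$db)

  g[c("embed", "enc_blocks", "dec_proj", "dec_blocks", "heads")]
}
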