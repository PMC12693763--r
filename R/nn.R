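# Neural-network primitives on base-R arrays + BLAS.
#
# Layout convention: activations are 3-D arrays dim (B, L, C) — batch
# fastest, then position, then channel — so dim<-(c(B*L, C)) reshapes to a
# matrix without copying semantics issues. Every layer has a forward
# returning list(out, cache) and a backward(dout, cache) returning the
# input gradient plus parameter gradients named like the parameters.

as_mat <- function(X) { d <- dim(X); dim(X) <- c(d[1L] * d[2L], d[3L]); X }
as_arr <- function(M, B, L) { dim(M) <- c(B, L, ncol(M)); M }

xavier_init <- function(fan_in, fan_out, dims) {
  a <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -a, a), dim = dims)
}

pad_BLC <- function(X, pl, pr) {
  if (pl == 0L && pr == 0L) return(X)
  d <- dim(X)
  Y <- array(0, dim = c(d[1L], d[2L] + pl + pr, d[3L]))
  Y[, (pl + 1L):(pl + d[2L]), ] <- X
  Y
}

# ---- 1-D convolution (kernel k, stride s, explicit padding) -------------

conv1d_forward <- function(X, W, b, stride = 1L, pad = NULL) {
  # X: (B, L, Cin); W: (k, Cin, Cout); b: (Cout)
  k <- dim(W)[1L]; cin <- dim(W)[2L]; cout <- dim(W)[3L]
  if (is.null(pad)) { pl <- (k - 1L) %/% 2L; pr <- k - 1L - pl }
  else { pl <- pad[1L]; pr <- pad[2L] }
  Xp <- pad_BLC(X, pl, pr)
  d <- dim(Xp); B <- d[1L]; Lp <- d[2L]
  Lout <- (Lp - k) %/% stride + 1L
  Y <- matrix(rep(b, each = B * Lout), B * Lout, cout)
  Xjs <- vector("list", k)  # kernel-offset slices, reused by backward
  for (j in seq_len(k)) {
    idx <- seq.int(j, by = stride, length.out = Lout)
    Xj <- Xp[, idx, , drop = FALSE]
    dim(Xj) <- c(B * Lout, cin)
    Xjs[[j]] <- Xj
    Y <- Y + Xj %*% matrix(W[j, , ], cin, cout)
  }
  out <- as_arr(Y, B, Lout)
  list(out = out,
       cache = list(Xjs = Xjs, dims = d, W = W, stride = stride, pl = pl,
                    Lin = dim(X)[2L], Lout = Lout))
}

conv1d_backward <- function(dY, cache) {
  W <- cache$W
  k <- dim(W)[1L]; cin <- dim(W)[2L]; cout <- dim(W)[3L]
  d <- cache$dims; B <- d[1L]
  Lout <- cache$Lout; stride <- cache$stride
  dYm <- as_mat(dY)
  dW <- array(0, dim = dim(W))
  db <- colSums(dYm)
  dXp <- array(0, dim = d)
  for (j in seq_len(k)) {
    idx <- seq.int(j, by = stride, length.out = Lout)
    dW[j, , ] <- crossprod(cache$Xjs[[j]], dYm)
    dXj <- dYm %*% t(matrix(W[j, , ], cin, cout))
    dim(dXj) <- c(B, Lout, cin)
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + dXj
  }
  pl <- cache$pl
  dX <- dXp[, (pl + 1L):(pl + cache$Lin), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# ---- batch normalization over (B, L) per channel ------------------------

batchnorm_forward <- function(X, gamma, beta, running, training,
                              momentum = 0.1, eps = 1e-5) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; C <- d[3L]
  Xm <- as_mat(X)
  if (training) {
    mu <- colMeans(Xm)
    var <- colMeans(Xm^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * var
  } else {
    mu <- running$mean; var <- running$var
  }
  inv <- 1 / sqrt(var + eps)
  Xh <- sweep(Xm, 2L, mu) %*% diag(inv, C)
  Y <- sweep(Xh %*% diag(gamma, C), 2L, beta, "+")
  list(out = as_arr(Y, B, L),
       cache = list(Xh = Xh, inv = inv, gamma = gamma, B = B, L = L,
                    training = training, mu = mu, var = var),
       running = running)
}

batchnorm_backward <- function(dY, cache) {
  dYm <- as_mat(dY)
  Xh <- cache$Xh; inv <- cache$inv; g <- cache$gamma
  n <- nrow(dYm); C <- ncol(dYm)
  dgamma <- colSums(dYm * Xh)
  dbeta <- colSums(dYm)
  dXh <- dYm %*% diag(g, C)
  if (cache$training) {
    dXm <- sweep(dXh - matrix(colMeans(dXh), n, C, byrow = TRUE) -
                   Xh * matrix(colMeans(dXh * Xh), n, C, byrow = TRUE),
                 2L, inv, "*")
  } else {
    dXm <- sweep(dXh, 2L, inv, "*")
  }
  list(dX = as_arr(dXm, cache$B, cache$L), dgamma = dgamma, dbeta = dbeta)
}

# ---- layer normalization over the channel axis per (b, l) ---------------

layernorm_forward <- function(X, gamma, beta, eps = 1e-5) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; C <- d[3L]
  Xm <- as_mat(X)
  mu <- rowMeans(Xm)
  va <- rowMeans(Xm^2) - mu^2
  inv <- 1 / sqrt(va + eps)
  Xh <- (Xm - mu) * inv
  Y <- sweep(Xh, 2L, gamma, "*")
  Y <- sweep(Y, 2L, beta, "+")
  list(out = as_arr(Y, B, L),
       cache = list(Xh = Xh, inv = inv, gamma = gamma, B = B, L = L))
}

layernorm_backward <- function(dY, cache) {
  dYm <- as_mat(dY)
  Xh <- cache$Xh; inv <- cache$inv; g <- cache$gamma
  C <- ncol(dYm)
  dgamma <- colSums(dYm * Xh)
  dbeta <- colSums(dYm)
  dXh <- sweep(dYm, 2L, g, "*")
  dXm <- (dXh - rowMeans(dXh) - Xh * rowMeans(dXh * Xh)) * inv
  list(dX = as_arr(dXm, cache$B, cache$L), dgamma = dgamma, dbeta = dbeta)
}

# ---- dense layers -------------------------------------------------------

linear_forward <- function(X, W, b) {
  arr <- length(dim(X)) == 3L
  Xm <- if (arr) as_mat(X) else X
  Y <- sweep(Xm %*% W, 2L, b, "+")
  if (arr) Y <- as_arr(Y, dim(X)[1L], dim(X)[2L])
  list(out = Y, cache = list(Xm = Xm, W = W, dims = dim(X)))
}

linear_backward <- function(dY, cache) {
  dYm <- if (length(dim(dY)) == 3L) as_mat(dY) else dY
  dW <- crossprod(cache$Xm, dYm)
  db <- colSums(dYm)
  dXm <- tcrossprod(dYm, cache$W)
  if (length(cache$dims) == 3L) dXm <- as_arr(dXm, cache$dims[1L], cache$dims[2L])
  list(dX = dXm, dW = dW, db = db)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}
relu_backward <- function(dY, mask) dY * mask

# ---- multi-head self-attention ------------------------------------------

row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

mhsa_forward <- function(X, p) {
  # X: (B, P, d); p: list(Wq,bq,Wk,bk,Wv,bv,Wo,bo,n_heads,head_dim)
  d <- dim(X); B <- d[1L]; P <- d[2L]
  h <- p$n_heads; dk <- p$head_dim
  q <- linear_forward(X, p$Wq, p$bq)
  k <- linear_forward(X, p$Wk, p$bk)
  v <- linear_forward(X, p$Wv, p$bv)
  Q <- q$out; K <- k$out; V <- v$out   # (B, P, h*dk)
  A <- array(0, dim = c(B, P, h * dk)) # concat of attention heads
  Att <- vector("list", B * h)         # softmax matrices for backward
  sc <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    Qb <- matrix(Q[b, , ], P); Kb <- matrix(K[b, , ], P); Vb <- matrix(V[b, , ], P)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      S <- tcrossprod(Qb[, cols, drop = FALSE], Kb[, cols, drop = FALSE]) * sc
      Pm <- row_softmax(S)
      A[b, , cols] <- Pm %*% Vb[, cols, drop = FALSE]
      Att[[(b - 1L) * h + hh]] <- Pm
    }
  }
  o <- linear_forward(A, p$Wo, p$bo)
  list(out = o$out,
       cache = list(q = q, k = k, v = v, o = o, Q = Q, K = K, V = V, A = A,
                    Att = Att, B = B, P = P, h = h, dk = dk))
}

mhsa_backward <- function(dY, cache, p) {
  B <- cache$B; P <- cache$P; h <- cache$h; dk <- cache$dk
  sc <- 1 / sqrt(dk)
  ob <- linear_backward(dY, cache$o$cache)
  dA <- ob$dX
  dQ <- array(0, dim = dim(cache$Q))
  dK <- array(0, dim = dim(cache$K))
  dV <- array(0, dim = dim(cache$V))
  for (b in seq_len(B)) {
    Qb <- matrix(cache$Q[b, , ], P); Kb <- matrix(cache$K[b, , ], P)
    Vb <- matrix(cache$V[b, , ], P); dAb <- matrix(dA[b, , ], P)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      Pm <- cache$Att[[(b - 1L) * h + hh]]
      dHead <- dAb[, cols, drop = FALSE]
      dPm <- tcrossprod(dHead, Vb[, cols, drop = FALSE])
      dV[b, , cols] <- crossprod(Pm, dHead)
      dS <- (dPm - rowSums(dPm * Pm)) * Pm * sc
      dQ[b, , cols] <- dS %*% Kb[, cols, drop = FALSE]
      dK[b, , cols] <- crossprod(dS, Qb[, cols, drop = FALSE])
    }
  }
  qb <- linear_backward(dQ, cache$q$cache)
  kb <- linear_backward(dK, cache$k$cache)
  vb <- linear_backward(dV, cache$v$cache)
  list(dX = qb$dX + kb$dX + vb$dX,
       grads = list(Wq = qb$dW, bq = qb$db, Wk = kb$dW, bk = kb$db,
                    Wv = vb$dW, bv = vb$db, Wo = ob$dW, bo = ob$db))
}

# ---- pre-norm Transformer block -----------------------------------------

block_forward <- function(X, p) {
  l1 <- layernorm_forward(X, p$ln1$gamma, p$ln1$beta)
  at <- mhsa_forward(l1$out, p$attn)
  X1 <- X + at$out
  l2 <- layernorm_forward(X1, p$ln2$gamma, p$ln2$beta)
  f1 <- linear_forward(l2$out, p$ffn$W1, p$ffn$b1)
  r1 <- relu_forward(f1$out)
  f2 <- linear_forward(r1$out, p$ffn$W2, p$ffn$b2)
  X2 <- X1 + f2$out
  list(out = X2, cache = list(l1 = l1, at = at, l2 = l2, f1 = f1,
                              r1 = r1, f2 = f2))
}

block_backward <- function(dY, cache, p) {
  f2b <- linear_backward(dY, cache$f2$cache)
  r1b <- relu_backward(f2b$dX, cache$r1$cache)
  f1b <- linear_backward(r1b, cache$f1$cache)
  l2b <- layernorm_backward(f1b$dX, cache$l2$cache)
  dX1 <- dY + l2b$dX
  atb <- mhsa_backward(dX1, cache$at$cache, p$attn)
  l1b <- layernorm_backward(atb$dX, cache$l1$cache)
  dX <- dX1 + l1b$dX
  list(dX = dX,
       grads = list(ln1 = list(gamma = l1b$dgamma, beta = l1b$dbeta),
                    attn = atb$grads,
                    ln2 = list(gamma = l2b$dgamma, beta = l2b$dbeta),
                    ffn = list(W1 = f1b$dW, b1 = f1b$db,
                               W2 = f2b$dW, b2 = f2b$db)))
}

init_block <- function(d_model, n_heads, head_dim, ffn_hidden) {
  dh <- n_heads * head_dim
  list(
    ln1 = list(gamma = rep(1, d_model), beta = rep(0, d_model)),
    attn = list(Wq = xavier_init(d_model, dh, c(d_model, dh)), bq = rep(0, dh),
                Wk = xavier_init(d_model, dh, c(d_model, dh)), bk = rep(0, dh),
                Wv = xavier_init(d_model, dh, c(d_model, dh)), bv = rep(0, dh),
                Wo = xavier_init(dh, d_model, c(dh, d_model)), bo = rep(0, d_model),
                n_heads = n_heads, head_dim = head_dim),
    ln2 = list(gamma = rep(1, d_model), beta = rep(0, d_model)),
    ffn = list(W1 = xavier_init(d_model, ffn_hidden, c(d_model, ffn_hidden)),
               b1 = rep(0, ffn_hidden),
               W2 = xavier_init(ffn_hidden, d_model, c(ffn_hidden, d_model)),
               b2 = rep(0, d_model))
  )
}

# ---- flatten parameters / gradients for the optimizer -------------------

NON_NUMERIC_PAR <- c("n_heads", "head_dim")

flatten_params <- function(p, prefix = "") {
  out <- list()
  keys <- names(p) %||% as.character(seq_along(p))
  if (is.null(names(p))) names(p) <- keys
  for (i in seq_along(p)) {
    nm <- keys[i]
    if (nm %in% NON_NUMERIC_PAR) next
    v <- p[[i]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else out[[key]] <- v
  }
  out
}

set_by_path <- function(p, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  rec <- function(node, parts) {
    key <- if (grepl("^[0-9]+$", parts[1L])) as.integer(parts[1L]) else parts[1L]
    if (length(parts) == 1L) { node[[key]] <- value; return(node) }
    node[[key]] <- rec(node[[key]], parts[-1L])
    node
  }
  rec(p, parts)
}

n_scalars <- function(p) sum(vapply(flatten_params(p), length, 0L))
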