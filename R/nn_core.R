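# Low-level neural-network primitives. Everything here operates on batches
# laid out column-major: a "batch matrix" has one column per example (or per
# token), so matrix products run once per layer, not once per example.
# Each *_forward returns its output plus the cache its *_backward needs;
# backward passes return input gradients and parameter gradients. Gradients
# are verified against central finite differences in the test suite.

init_uniform <- function(nr, nc, fan_in = nc, fan_out = nr) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# --- im2col convolution -----------------------------------------------------

# Precomputed gather indices turning a valid (unpadded) strided 2-D
# convolution over a (C, H, W) tensor into one matrix product.
# Patch rows are ordered channel-fastest, matching a weight matrix of shape
# (filters x C*k*k).
im2col_index <- function(in_shape, k, stride) {
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  out_h <- (H - k) %/% stride + 1L
  out_w <- (W - k) %/% stride + 1L
  check_arg(out_h >= 1 && out_w >= 1, "kernel does not fit input")
  idx <- matrix(0L, C * k * k, out_h * out_w)
  p <- 0L
  for (j in seq_len(out_w)) {
    for (i in seq_len(out_h)) {
      p <- p + 1L
      r <- 0L
      for (kw in seq_len(k)) {
        for (kh in seq_len(k)) {
          h <- (i - 1L) * stride + kh
          w <- (j - 1L) * stride + kw
          idx[r + seq_len(C), p] <- seq_len(C) + C * (h - 1L) + C * H * (w - 1L)
          r <- r + C
        }
      }
    }
  }
  list(idx = idx, out_h = out_h, out_w = out_w,
       n_pos = out_h * out_w, in_len = C * H * W, patch = C * k * k)
}

# Xf: (C*H*W) x B flattened inputs; W: (F x patch); returns (F x n_pos*B).
conv2d_forward <- function(Xf, W, b, im) {
  B <- ncol(Xf)
  Xcol <- Xf[as.vector(im$idx), , drop = FALSE]
  dim(Xcol) <- c(im$patch, im$n_pos * B)
  list(out = W %*% Xcol + b, Xcol = Xcol, B = B)
}

conv2d_backward <- function(dZ, cache, W, im, need_dx = TRUE) {
  dW <- dZ %*% t(cache$Xcol)
  db <- rowSums(dZ)
  dXf <- NULL
  if (need_dx) {
    dXcol <- crossprod(W, dZ)
    dim(dXcol) <- c(im$patch * im$n_pos, cache$B)
    rs <- rowsum(dXcol, group = as.vector(im$idx))
    dXf <- matrix(0, im$in_len, cache$B)
    dXf[as.integer(rownames(rs)), ] <- rs
  }
  list(dX = dXf, dW = dW, db = db)
}

# --- misc batched helpers ---------------------------------------------------

# Mean over the middle dimension of an (F, P, B) stack held as an F x (P*B)
# matrix; returns F x B.
pool_middle <- function(M, F_, P, B) {
  dim(M) <- c(F_ * P, B)
  out <- rowsum(M, group = rep_len(seq_len(F_), F_ * P), reorder = FALSE) / P
  dimnames(out) <- NULL
  out
}

# Expand an (F x B) per-channel factor to an F x (P*B) matrix (constant over
# the P positions of each example).
expand_middle <- function(S, P, B) S[, rep(seq_len(B), each = P), drop = FALSE]

# --- layer normalisation (tokens in columns) --------------------------------

layernorm_forward <- function(X, g, b, eps = 1e-5) {
  d <- nrow(X)
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  sdv <- sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2, sdv, "/")
  list(out = xhat * g + b, xhat = xhat, sdv = sdv)
}

layernorm_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- rowSums(dY * xhat)
  db <- rowSums(dY)
  dxh <- dY * g
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * xhat)
  dX <- sweep(sweep(dxh, 2, m1) - sweep(xhat, 2, m2, "*"), 2, cache$sdv, "/")
  list(dX = dX, dg = dg, db = db)
}

# --- capsule squash ---------------------------------------------------------

# v = s * ||s|| / (1 + ||s||^2), applied to each column vector; the canonical
# capsule nonlinearity mapping norms into [0, 1).
squash_cols <- function(S) {
  n2 <- colSums(S^2)
  sc <- sqrt(n2) / (1 + n2)
  list(out = S * rep(sc, each = nrow(S)), n2 = n2, sc = sc)
}

squash_cols_backward <- function(dV, S, cache) {
  d <- nrow(S)
  n2 <- cache$n2
  n <- sqrt(n2)
  st <- colSums(S * dV)
  coef <- ifelse(n > 1e-12, (1 - n2) / ((1 + n2)^2 * n), 0)
  dV * rep(cache$sc, each = d) + S * rep(coef * st, each = d)
}

# --- dropout ----------------------------------------------------------------

dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, mask = NULL))
  mask <- (matrix(stats::runif(length(X)), nrow(X)) >= p) / (1 - p)
  list(out = X * mask, mask = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
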