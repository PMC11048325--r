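#' Capsule-network configuration
#'
#' The intra-slice encoder maps one 3 x 16 x 18 multi-domain feature map to
#' one 16-D emotion capsule per class: a stride-2 valid 3 x 3 convolution with
#' ReLU (256 filters in the full model), an ECA channel-attention block, a
#' bank of stride-1 3 x 3 capsule convolutions forming
#' `primary_caps_channels` capsule channels of dimension `primary_caps_dim`
#' (with an SE block on the convolutional planes before capsule regrouping),
#' and dynamic routing into `n_classes` emotion capsules of dimension
#' `emotion_caps_dim`.
#'
#' With the 3 x 16 x 18 input, the stride-2 valid convolution yields a
#' 7 x 8 grid, the stride-1 capsule convolution a 5 x 6 grid, hence
#' `primary_caps_channels * 5 * 6` primary capsules (960 in the full model).
#'
#' @param n_classes 2 or 3 emotion classes.
#' @param conv_out_channels First-layer filter count; must equal
#'   `primary_caps_channels * primary_caps_dim` so the capsule stage consumes
#'   the convolutional stack cleanly.
#' @param primary_caps_channels,primary_caps_dim Capsule channel count and
#'   per-capsule dimension of the primary capsule layer.
#' @param emotion_caps_dim Dimension of each class capsule (16).
#' @param routing_iters Dynamic-routing iterations (>= 1; default 3).
#' @param eca_gamma,eca_b Offsets of the ECA kernel-size mapping.
#' @param se_reduction Bottleneck reduction ratio of the SE block.
#' @param use_eca,use_se Ablation switches for the attention blocks.
#' @param in_shape Input tensor shape (3, 16, 18).
#' @return An object of class `capsnet_config` with derived shape fields.
#' @export
capsnet_config <- function(n_classes = 2, conv_out_channels = 256,
                           primary_caps_channels = 32, primary_caps_dim = 8,
                           emotion_caps_dim = 16, routing_iters = 3,
                           eca_gamma = 2, eca_b = 1, se_reduction = 16,
                           use_eca = TRUE, use_se = TRUE,
                           in_shape = c(3, 16, 18)) {
  check_arg(n_classes %in% c(2, 3), "n_classes must be 2 or 3")
  check_arg(routing_iters >= 1, "routing_iters must be >= 1")
  check_arg(primary_caps_channels * primary_caps_dim == conv_out_channels,
            "primary_caps_channels * primary_caps_dim must equal conv_out_channels")
  check_arg(conv_out_channels >= se_reduction,
            "conv_out_channels must be >= se_reduction")
  im1 <- im2col_index(in_shape, 3L, 2L)
  im2 <- im2col_index(c(conv_out_channels, im1$out_h, im1$out_w), 3L, 1L)
  cfg <- list(n_classes = as.integer(n_classes),
              conv_out_channels = as.integer(conv_out_channels),
              primary_caps_channels = as.integer(primary_caps_channels),
              primary_caps_dim = as.integer(primary_caps_dim),
              emotion_caps_dim = as.integer(emotion_caps_dim),
              routing_iters = as.integer(routing_iters),
              eca_gamma = eca_gamma, eca_b = eca_b,
              se_reduction = as.integer(se_reduction),
              use_eca = isTRUE(use_eca), use_se = isTRUE(use_se),
              in_shape = as.integer(in_shape),
              im1 = im1, im2 = im2,
              n_primary = as.integer(primary_caps_channels * im2$n_pos),
              se_hidden = max(1L, conv_out_channels %/% se_reduction))
  class(cfg) <- "capsnet_config"
  cfg
}

#' Adaptive ECA kernel size
#'
#' `t = |log2(C)/gamma + b/gamma|`, rounded to the nearest odd integer from
#' below: `k = floor(t)` if odd, else `floor(t) + 1`, with `k >= 1`. The
#' channel-adaptive 1-D convolution width of the ECA block.
#'
#' @param C Channel count (>= 1).
#' @param gamma,b Mapping offsets (defaults 2 and 1).
#' @return An odd integer.
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  check_arg(C >= 1, "C must be >= 1")
  t <- abs(log2(C) / gamma + b / gamma)
  k <- if (floor(t) %% 2 == 1) floor(t) else floor(t) + 1
  as.integer(max(1, k))
}

# zero-padded row shift: out[f, ] = m[f + off, ] (0 outside)
shift_rows <- function(m, off) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  src <- seq_len(n) + off
  ok <- src >= 1 & src <= n
  out[ok, ] <- m[src[ok], , drop = FALSE]
  out
}

# --- ECA block --------------------------------------------------------------
# x held as (C x P*B); global average pool per channel, 1-D convolution of
# odd size k over the channel axis, sigmoid gate multiplying the input.

eca_forward <- function(X, w, C, P, B) {
  g <- pool_middle(X, C, P, B)
  k <- length(w)
  h <- (k - 1L) %/% 2L
  y <- matrix(0, C, B)
  for (t in seq_len(k)) y <- y + w[t] * shift_rows(g, t - 1L - h)
  s <- sigmoid(y)
  list(out = X * expand_middle(s, P, B), g = g, s = s)
}

eca_backward <- function(dOut, X, w, cache, C, P, B) {
  k <- length(w)
  h <- (k - 1L) %/% 2L
  s <- cache$s
  dX <- dOut * expand_middle(s, P, B)
  ds <- pool_middle(dOut * X, C, P, B) * P     # sum, not mean
  dy <- ds * s * (1 - s)
  dw <- numeric(k)
  dg <- matrix(0, C, B)
  for (t in seq_len(k)) {
    dw[t] <- sum(dy * shift_rows(cache$g, t - 1L - h))
    dg <- dg + w[t] * shift_rows(dy, -(t - 1L - h))
  }
  dX <- dX + expand_middle(dg / P, P, B)
  list(dX = dX, dw = dw)
}

# --- SE block ---------------------------------------------------------------
# squeeze: per-channel spatial mean; excite: sigmoid(W2 relu(W1 z)); scale.

se_forward <- function(X, W1, W2, C, P, B) {
  z <- pool_middle(X, C, P, B)
  h1 <- relu(W1 %*% z)
  s <- sigmoid(W2 %*% h1)
  list(out = X * expand_middle(s, P, B), z = z, h1 = h1, s = s)
}

se_backward <- function(dOut, X, W1, W2, cache, C, P, B) {
  s <- cache$s
  dX <- dOut * expand_middle(s, P, B)
  ds <- pool_middle(dOut * X, C, P, B) * P
  da <- ds * s * (1 - s)
  dW2 <- da %*% t(cache$h1)
  dh1 <- crossprod(W2, da) * (cache$h1 > 0)
  dW1 <- dh1 %*% t(cache$z)
  dz <- crossprod(W1, dh1)
  dX <- dX + expand_middle(dz / P, P, B)
  list(dX = dX, dW1 = dW1, dW2 = dW2)
}

#' Standalone SE block on a C x H x W tensor
#'
#' Reference single-example interface to the squeeze-and-excitation block used
#' inside the primary capsule layer (the training path runs the batched
#' internal version with the same arithmetic).
#'
#' @param x A 3-D array (channels, height, width).
#' @param W1 Bottleneck weight matrix (`C/r` x `C`).
#' @param W2 Expansion weight matrix (`C` x `C/r`).
#' @return An array shaped like `x`, channel-reweighted.
#' @export
se_block <- function(x, W1, W2) {
  d <- dim(x)
  check_arg(length(d) == 3, "x must be a C x H x W array")
  check_arg(ncol(W1) == d[1] && nrow(W2) == d[1] && nrow(W1) == ncol(W2),
            "SE weight shapes inconsistent with channel count")
  X <- matrix(x, d[1])
  out <- se_forward(X, W1, W2, d[1], d[2] * d[3], 1L)$out
  array(out, d)
}

#' Standalone ECA block on a C x H x W tensor
#'
#' @param x A 3-D array (channels, height, width).
#' @param w 1-D convolution weights of odd length `k` (see
#'   [eca_kernel_size()]).
#' @return An array shaped like `x`, channel-reweighted.
#' @export
eca_block <- function(x, w) {
  d <- dim(x)
  check_arg(length(d) == 3, "x must be a C x H x W array")
  check_arg(length(w) %% 2 == 1, "ECA kernel length must be odd")
  X <- matrix(x, d[1])
  out <- eca_forward(X, w, d[1], d[2] * d[3], 1L)$out
  array(out, d)
}

#' Capsule squash nonlinearity
#'
#' `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`, with `v = 0` at `s = 0`:
#' direction preserved, norm mapped monotonically into `[0, 1)`.
#'
#' @param s Numeric vector, or a matrix whose columns are squashed
#'   independently.
#' @return Same shape as `s`.
#' @export
squash <- function(s) {
  if (is.matrix(s)) squash_cols(s)$out else as.vector(squash_cols(cbind(s))$out)
}

# --- dynamic routing --------------------------------------------------------
# ulist: per-class-capsule prediction vectors u_hat as a list over j of
# (N x ed x B) arrays. Coupling logits start at zero (uniform coupling);
# each iteration reassigns primary capsules toward the class capsules they
# agree with. Returns squashed class capsules and the full per-iteration
# cache needed for unrolled backpropagation.

# sum over e: M holds (N, ed, B); w holds (ed, B) -> (N, B)
routing_contract_e <- function(M, w, N, ed, B) {
  Mv <- matrix(M, N) * rep(as.vector(w), each = N)
  dim(Mv) <- c(N * ed, B)
  out <- rowsum(Mv, group = rep_len(seq_len(N), N * ed), reorder = FALSE)
  dimnames(out) <- NULL
  out
}

# sum over i: M holds (N, ed, B); w holds (N, B) -> (ed, B)
routing_contract_i <- function(M, w, N, ed, B) {
  Cb <- w[, rep(seq_len(B), each = ed), drop = FALSE]
  matrix(colSums(matrix(M, N) * Cb), ed, B)
}

# outer product per (e, b): w (N, B), z (ed, B) -> (N, ed, B)
routing_outer <- function(w, z, N, ed, B) {
  out <- w[, rep(seq_len(B), each = ed), drop = FALSE] *
    rep(as.vector(z), each = N)
  dim(out) <- c(N, ed, B)
  out
}

routing_forward <- function(ulist, n_iters) {
  J <- length(ulist)
  N <- dim(ulist[[1]])[1]
  ed <- dim(ulist[[1]])[2]
  B <- dim(ulist[[1]])[3]
  blist <- rep(list(matrix(0, N, B)), J)
  iters <- vector("list", n_iters)
  vlist <- NULL
  for (it in seq_len(n_iters)) {
    mx <- Reduce(pmax, blist)
    elist <- lapply(blist, function(b) exp(b - mx))
    den <- Reduce(`+`, elist)
    clist <- lapply(elist, function(e) e / den)
    slist <- lapply(seq_len(J), function(j) {
      routing_contract_i(ulist[[j]], clist[[j]], N, ed, B)
    })
    sq <- lapply(slist, squash_cols)
    vlist <- lapply(sq, `[[`, "out")
    iters[[it]] <- list(clist = clist, slist = slist, vlist = vlist,
                        sq = lapply(sq, function(x) x[c("n2", "sc")]))
    if (it < n_iters) {
      for (j in seq_len(J)) {
        blist[[j]] <- blist[[j]] +
          routing_contract_e(ulist[[j]], vlist[[j]], N, ed, B)
      }
    }
  }
  list(vlist = vlist, iters = iters, dims = c(N = N, ed = ed, B = B, J = J))
}

routing_backward <- function(dvlist, ulist, cache) {
  dm <- cache$dims
  N <- dm["N"]; ed <- dm["ed"]; B <- dm["B"]; J <- dm["J"]
  n_iters <- length(cache$iters)
  du <- rep(list(array(0, c(N, ed, B))), J)
  db <- rep(list(matrix(0, N, B)), J)
  dv <- dvlist
  for (it in rev(seq_len(n_iters))) {
    st <- cache$iters[[it]]
    dc <- vector("list", J)
    for (j in seq_len(J)) {
      ds <- squash_cols_backward(dv[[j]], st$slist[[j]], st$sq[[j]])
      dc[[j]] <- routing_contract_e(ulist[[j]], ds, N, ed, B)
      du[[j]] <- du[[j]] + routing_outer(st$clist[[j]], ds, N, ed, B)
    }
    inner <- Reduce(`+`, lapply(seq_len(J), function(j) st$clist[[j]] * dc[[j]]))
    for (j in seq_len(J)) {
      db[[j]] <- db[[j]] + st$clist[[j]] * (dc[[j]] - inner)
    }
    if (it > 1) {
      vprev <- cache$iters[[it - 1]]$vlist
      dv <- vector("list", J)
      for (j in seq_len(J)) {
        du[[j]] <- du[[j]] + routing_outer(db[[j]], vprev[[j]], N, ed, B)
        dv[[j]] <- routing_contract_i(ulist[[j]], db[[j]], N, ed, B)
      }
    }
  }
  du
}

#' Dynamic routing between capsule layers
#'
#' Routing-by-agreement: prediction vectors `u_hat[j|i] = W[i,j] u[i]` are
#' combined with coupling coefficients that start uniform (softmax of zero
#' logits) and are sharpened over `n_iters` iterations by the scalar
#' agreement between each prediction and the squashed class capsule.
#'
#' @param primary N x d matrix of primary capsule vectors (rows are capsules).
#' @param weights Array of per-pair transforms, dim
#'   `(n_out * out_dim, d, N)`: `weights[, , i]` maps capsule `i`'s vector to
#'   the stacked predictions for all output capsules.
#' @param n_out Number of output (class) capsules.
#' @param n_iters Routing iterations (>= 1).
#' @return An `n_out x out_dim` matrix of squashed class capsule vectors
#'   (Euclidean norms in `[0, 1)`).
#' @export
dynamic_routing <- function(primary, weights, n_out, n_iters = 3) {
  check_arg(n_iters >= 1, "n_iters must be >= 1")
  N <- nrow(primary)
  d <- ncol(primary)
  check_arg(dim(weights)[2] == d && dim(weights)[3] == N,
            "weights must have dim (n_out*out_dim, d, N)")
  ed <- dim(weights)[1] %/% n_out
  U4 <- array(0, c(n_out * ed, N, 1))
  for (i in seq_len(N)) U4[, i, 1] <- weights[, , i] %*% primary[i, ]
  ulist <- lapply(seq_len(n_out), function(j) {
    aperm(U4[(j - 1) * ed + seq_len(ed), , , drop = FALSE], c(2, 1, 3))
  })
  rf <- routing_forward(ulist, n_iters)
  t(vapply(rf$vlist, function(v) v[, 1], numeric(ed)))
}

# --- full capsnet forward/backward (batched) --------------------------------

capsnet_init <- function(cfg) {
  F1 <- cfg$conv_out_channels
  O2 <- cfg$primary_caps_channels * cfg$primary_caps_dim
  J <- cfg$n_classes
  ed <- cfg$emotion_caps_dim
  pd <- cfg$primary_caps_dim
  N <- cfg$n_primary
  p <- list(
    conv1_W = init_uniform(F1, cfg$im1$patch),
    conv1_b = numeric(F1),
    pconv_W = init_uniform(O2, cfg$im2$patch),
    pconv_b = numeric(O2),
    route_W = array(stats::runif(J * ed * pd * N, -0.1, 0.1), c(J * ed, pd, N))
  )
  if (cfg$use_eca) {
    p$eca_w <- stats::runif(eca_kernel_size(F1, cfg$eca_gamma, cfg$eca_b), -0.5, 0.5)
  }
  if (cfg$use_se) {
    p$se_W1 <- init_uniform(cfg$se_hidden, O2)
    p$se_W2 <- init_uniform(O2, cfg$se_hidden)
  }
  p
}

# Xf: (3*16*18) x B. Returns token matrix (J*ed x B) of flattened class
# capsules plus cache.
capsnet_forward <- function(params, Xf, cfg) {
  check_arg(nrow(Xf) == prod(cfg$in_shape), "input shape mismatch")
  B <- ncol(Xf)
  F1 <- cfg$conv_out_channels
  P1 <- cfg$im1$n_pos
  O2 <- cfg$primary_caps_channels * cfg$primary_caps_dim
  P2 <- cfg$im2$n_pos
  pd <- cfg$primary_caps_dim
  pc <- cfg$primary_caps_channels
  N <- cfg$n_primary
  J <- cfg$n_classes
  ed <- cfg$emotion_caps_dim

  c1 <- conv2d_forward(Xf, params$conv1_W, params$conv1_b, cfg$im1)
  A1 <- relu(c1$out)
  eca <- NULL
  A1e <- A1
  if (cfg$use_eca) {
    eca <- eca_forward(A1, params$eca_w, F1, P1, B)
    A1e <- eca$out
  }
  A1f <- A1e
  dim(A1f) <- c(F1 * P1, B) # (channel, pos) pairs become the flat input axis
  c2 <- conv2d_forward(A1f, params$pconv_W, params$pconv_b, cfg$im2)
  Z2 <- c2$out
  se <- NULL
  Z2e <- Z2
  if (cfg$use_se) {
    se <- se_forward(Z2, params$se_W1, params$se_W2, O2, P2, B)
    Z2e <- se$out
  }
  # regroup planes (pd fastest within capsule channel) into capsules
  U <- Z2e
  dim(U) <- c(pd, pc, P2, B)
  dim(U) <- c(pd, N, B)
  sqp <- squash_cols(matrix(U, pd))
  Us <- array(sqp$out, c(pd, N, B))
  # prediction vectors per primary capsule
  U4 <- array(0, c(J * ed, N, B))
  for (i in seq_len(N)) U4[, i, ] <- params$route_W[, , i] %*% Us[, i, ]
  ulist <- lapply(seq_len(J), function(j) {
    aperm(U4[(j - 1) * ed + seq_len(ed), , , drop = FALSE], c(2, 1, 3))
  })
  rf <- routing_forward(ulist, cfg$routing_iters)
  tokens <- do.call(rbind, rf$vlist)
  list(out = tokens,
       cache = list(B = B, c1 = c1, A1 = A1, eca = eca, A1e = A1e,
                    c2 = c2, Z2 = Z2, se = se, U = U, sqp = sqp, Us = Us,
                    ulist = ulist, rf = rf))
}

capsnet_backward <- function(dtok, params, cfg, cache) {
  B <- cache$B
  F1 <- cfg$conv_out_channels
  P1 <- cfg$im1$n_pos
  O2 <- cfg$primary_caps_channels * cfg$primary_caps_dim
  P2 <- cfg$im2$n_pos
  pd <- cfg$primary_caps_dim
  pc <- cfg$primary_caps_channels
  N <- cfg$n_primary
  J <- cfg$n_classes
  ed <- cfg$emotion_caps_dim
  grads <- list()

  dvlist <- lapply(seq_len(J), function(j) {
    dtok[(j - 1) * ed + seq_len(ed), , drop = FALSE]
  })
  du <- routing_backward(dvlist, cache$ulist, cache$rf)
  # back through prediction transforms
  dU4 <- array(0, c(J * ed, N, B))
  for (j in seq_len(J)) {
    dU4[(j - 1) * ed + seq_len(ed), , ] <- aperm(du[[j]], c(2, 1, 3))
  }
  dWr <- array(0, dim(params$route_W))
  dUs <- array(0, c(pd, N, B))
  for (i in seq_len(N)) {
    dWr[, , i] <- dU4[, i, ] %*% t(cache$Us[, i, ])
    dUs[, i, ] <- crossprod(params$route_W[, , i], dU4[, i, ])
  }
  grads$route_W <- dWr
  dU <- squash_cols_backward(matrix(dUs, pd), matrix(cache$U, pd), cache$sqp)
  dZ2e <- dU
  dim(dZ2e) <- c(O2, P2 * B)
  if (cfg$use_se) {
    seb <- se_backward(dZ2e, cache$Z2, params$se_W1, params$se_W2,
                       cache$se, O2, P2, B)
    grads$se_W1 <- seb$dW1
    grads$se_W2 <- seb$dW2
    dZ2 <- seb$dX
  } else {
    dZ2 <- dZ2e
  }
  c2b <- conv2d_backward(dZ2, cache$c2, params$pconv_W, cfg$im2)
  grads$pconv_W <- c2b$dW
  grads$pconv_b <- c2b$db
  dA1e <- c2b$dX
  dim(dA1e) <- c(F1, P1 * B)
  if (cfg$use_eca) {
    eb <- eca_backward(dA1e, cache$A1, params$eca_w, cache$eca, F1, P1, B)
    grads$eca_w <- eb$dw
    dA1 <- eb$dX
  } else {
    dA1 <- dA1e
  }
  dZ1 <- dA1 * (cache$c1$out > 0)
  c1b <- conv2d_backward(dZ1, cache$c1, params$conv1_W, cfg$im1, need_dx = FALSE)
  grads$conv1_W <- c1b$dW
  grads$conv1_b <- c1b$db
  grads
}
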