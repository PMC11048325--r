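#' Temporal encoder configuration
#'
#' The inter-slice encoder: per-slice class-capsule vectors are flattened to
#' `d_model = n_classes * emotion_caps_dim` tokens, the `T` tokens of one
#' recognition-cycle sample form a sequence, and a stack of `n_layers`
#' post-norm encoder layers (multi-head self-attention + feed-forward, each
#' with residual connection and layer normalisation) recodes them before the
#' softmax classifier reads all `T` encoded tokens.
#'
#' @param d_model Token width (`n_classes * 16` in the full model; divisible
#'   by `n_heads`).
#' @param n_layers Number of encoder layers (6).
#' @param n_heads Attention heads per layer (8).
#' @param ffn_hidden Feed-forward hidden width (default `4 * d_model`).
#' @param dropout Dropout fraction applied to sublayer outputs during
#'   training.
#' @param T Slices per sample (4).
#' @param positional_encoding `"sinusoidal"` (default — temporal order is the
#'   point of this stage) or `"none"` (ablation).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(d_model, n_layers = 6, n_heads = 8,
                           ffn_hidden = NULL, dropout = 0.1, T = 4,
                           positional_encoding = c("sinusoidal", "none")) {
  check_arg(d_model %% n_heads == 0, "d_model must be divisible by n_heads")
  check_arg(T >= 1, "T must be >= 1")
  if (is.null(ffn_hidden)) ffn_hidden <- 4L * d_model
  structure(list(d_model = as.integer(d_model), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), ffn_hidden = as.integer(ffn_hidden),
                 dropout = as.numeric(dropout), T = as.integer(T),
                 positional_encoding = match.arg(positional_encoding)),
            class = "encoder_config")
}

#' Flatten per-slice emotion vectors into a token sequence
#'
#' Each slice's `n_classes x dim` capsule matrix is flattened row-major into
#' one token; tokens are stacked in slice order.
#'
#' @param ev List of `T` matrices (`n_classes x dim`), temporally ordered.
#' @return A `T x (n_classes*dim)` matrix (one token per row).
#' @export
flatten_slices <- function(ev) {
  check_arg(length(ev) >= 1, "need at least one slice")
  dims <- vapply(ev, dim, integer(2))
  check_arg(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
            "inconsistent capsule dimensions across slices")
  t(vapply(ev, function(m) as.vector(t(m)), numeric(length(ev[[1]]))))
}

#' Scaled dot-product attention
#'
#' `A = softmax(Q K' / sqrt(d_k)) V`, softmax taken over each query's row so
#' every attention row sums to one.
#'
#' @param Q,K,V Matrices with one token per row; `Q` and `K` share width
#'   `d_k`, `K` and `V` share their token count.
#' @param d_k Key width used in the temperature (defaults to `ncol(K)`).
#' @return A matrix of `nrow(Q)` rows.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  check_arg(ncol(Q) == ncol(K), "Q and K widths differ")
  check_arg(nrow(K) == nrow(V), "K and V token counts differ")
  S <- Q %*% t(K) / sqrt(d_k)
  P <- t(softmax_cols(t(S)))
  P %*% V
}

# sinusoidal positional encoding, one column per position: (d x T)
positional_encoding_matrix <- function(d, T) {
  pe <- matrix(0, d, T)
  pos <- seq_len(T) - 1
  for (i in seq_len(ceiling(d / 2))) {
    ang <- pos / 10000^((2 * (i - 1)) / d)
    pe[2 * i - 1, ] <- sin(ang)
    if (2 * i <= d) pe[2 * i, ] <- cos(ang)
  }
  pe
}

# --- batched internals ------------------------------------------------------
# Tokens live in columns: X is (d x M) with M = T*B, slice index fastest, so
# column (t, b) is token t of sample b.

enc_par <- function(l, nm) paste0("enc", l, "_", nm)

encoder_init <- function(cfg) {
  d <- cfg$d_model
  p <- list()
  for (l in seq_len(cfg$n_layers)) {
    p[[enc_par(l, "Wq")]] <- init_uniform(d, d)
    p[[enc_par(l, "Wk")]] <- init_uniform(d, d)
    p[[enc_par(l, "Wv")]] <- init_uniform(d, d)
    p[[enc_par(l, "Wo")]] <- init_uniform(d, d)
    p[[enc_par(l, "bo")]] <- numeric(d)
    p[[enc_par(l, "ln1_g")]] <- rep(1, d)
    p[[enc_par(l, "ln1_b")]] <- numeric(d)
    p[[enc_par(l, "ffn_W1")]] <- init_uniform(cfg$ffn_hidden, d)
    p[[enc_par(l, "ffn_b1")]] <- numeric(cfg$ffn_hidden)
    p[[enc_par(l, "ffn_W2")]] <- init_uniform(d, cfg$ffn_hidden)
    p[[enc_par(l, "ffn_b2")]] <- numeric(d)
    p[[enc_par(l, "ln2_g")]] <- rep(1, d)
    p[[enc_par(l, "ln2_b")]] <- numeric(d)
  }
  p
}

slice_tok <- function(A, rows, i) matrix(A[rows, i, ], length(rows), dim(A)[3])

mhsa_forward <- function(X, Wq, Wk, Wv, Wo, bo, n_heads, T, B) {
  d <- nrow(X)
  dk <- d %/% n_heads
  scal <- 1 / sqrt(dk)
  Qa <- array(Wq %*% X, c(d, T, B))
  Ka <- array(Wk %*% X, c(d, T, B))
  Va <- array(Wv %*% X, c(d, T, B))
  O <- array(0, c(d, T, B))
  Plist <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    rh <- (h - 1L) * dk + seq_len(dk)
    P <- array(0, c(T, T, B))
    for (i in seq_len(T)) {
      Qi <- slice_tok(Qa, rh, i)
      S <- matrix(0, T, B)
      for (j in seq_len(T)) S[j, ] <- colSums(Qi * slice_tok(Ka, rh, j)) * scal
      P[i, , ] <- softmax_cols(S)
    }
    for (i in seq_len(T)) {
      Oi <- matrix(0, dk, B)
      for (j in seq_len(T)) {
        Oi <- Oi + slice_tok(Va, rh, j) * rep(matrix(P[i, j, ], 1, B), each = dk)
      }
      O[rh, i, ] <- Oi
    }
    Plist[[h]] <- P
  }
  Omat <- matrix(O, d)
  list(out = Wo %*% Omat + bo,
       cache = list(Qa = Qa, Ka = Ka, Va = Va, O = Omat, P = Plist,
                    T = T, B = B))
}

mhsa_backward <- function(dOut, X, Wq, Wk, Wv, Wo, cache, n_heads) {
  d <- nrow(X)
  T <- cache$T
  B <- cache$B
  dk <- d %/% n_heads
  scal <- 1 / sqrt(dk)
  dWo <- dOut %*% t(cache$O)
  dbo <- rowSums(dOut)
  dO <- array(crossprod(Wo, dOut), c(d, T, B))
  dQ <- array(0, c(d, T, B))
  dK <- array(0, c(d, T, B))
  dV <- array(0, c(d, T, B))
  for (h in seq_len(n_heads)) {
    rh <- (h - 1L) * dk + seq_len(dk)
    P <- cache$P[[h]]
    for (i in seq_len(T)) {
      dOi <- slice_tok(dO, rh, i)
      dPi <- matrix(0, T, B)
      for (j in seq_len(T)) {
        Vj <- slice_tok(cache$Va, rh, j)
        dPi[j, ] <- colSums(dOi * Vj)
        dV[rh, j, ] <- slice_tok(dV, rh, j) +
          dOi * rep(matrix(P[i, j, ], 1, B), each = dk)
      }
      Pi <- matrix(P[i, , ], T, B)
      dSi <- Pi * sweep(dPi, 2, colSums(Pi * dPi))
      Qi <- slice_tok(cache$Qa, rh, i)
      dQi <- matrix(0, dk, B)
      for (j in seq_len(T)) {
        w <- rep(matrix(dSi[j, ], 1, B), each = dk) * scal
        dQi <- dQi + slice_tok(cache$Ka, rh, j) * w
        dK[rh, j, ] <- slice_tok(dK, rh, j) + Qi * w
      }
      dQ[rh, i, ] <- dQi
    }
  }
  dQm <- matrix(dQ, d)
  dKm <- matrix(dK, d)
  dVm <- matrix(dV, d)
  list(dX = crossprod(Wq, dQm) + crossprod(Wk, dKm) + crossprod(Wv, dVm),
       dWq = dQm %*% t(X), dWk = dKm %*% t(X), dWv = dVm %*% t(X),
       dWo = dWo, dbo = dbo)
}

encoder_layer_forward <- function(X, params, l, cfg, B, training = FALSE) {
  g <- function(nm) params[[enc_par(l, nm)]]
  at <- mhsa_forward(X, g("Wq"), g("Wk"), g("Wv"), g("Wo"), g("bo"),
                     cfg$n_heads, cfg$T, B)
  dr1 <- dropout_forward(at$out, cfg$dropout, training)
  ln1 <- layernorm_forward(X + dr1$out, g("ln1_g"), g("ln1_b"))
  X1 <- ln1$out
  H1p <- g("ffn_W1") %*% X1 + g("ffn_b1")
  H1 <- relu(H1p)
  FF <- g("ffn_W2") %*% H1 + g("ffn_b2")
  dr2 <- dropout_forward(FF, cfg$dropout, training)
  ln2 <- layernorm_forward(X1 + dr2$out, g("ln2_g"), g("ln2_b"))
  list(out = ln2$out,
       cache = list(X = X, at = at, dr1 = dr1, ln1 = ln1, X1 = X1,
                    H1p = H1p, H1 = H1, dr2 = dr2, ln2 = ln2))
}

encoder_layer_backward <- function(dY, params, l, cfg, cache) {
  g <- function(nm) params[[enc_par(l, nm)]]
  grads <- list()
  l2 <- layernorm_backward(dY, cache$ln2, g("ln2_g"))
  grads[[enc_par(l, "ln2_g")]] <- l2$dg
  grads[[enc_par(l, "ln2_b")]] <- l2$db
  dX1 <- l2$dX
  dFF <- dropout_backward(l2$dX, cache$dr2)
  grads[[enc_par(l, "ffn_W2")]] <- dFF %*% t(cache$H1)
  grads[[enc_par(l, "ffn_b2")]] <- rowSums(dFF)
  dH1 <- crossprod(g("ffn_W2"), dFF) * (cache$H1p > 0)
  grads[[enc_par(l, "ffn_W1")]] <- dH1 %*% t(cache$X1)
  grads[[enc_par(l, "ffn_b1")]] <- rowSums(dH1)
  dX1 <- dX1 + crossprod(g("ffn_W1"), dH1)
  l1 <- layernorm_backward(dX1, cache$ln1, g("ln1_g"))
  grads[[enc_par(l, "ln1_g")]] <- l1$dg
  grads[[enc_par(l, "ln1_b")]] <- l1$db
  dA <- dropout_backward(l1$dX, cache$dr1)
  mb <- mhsa_backward(dA, cache$X, g("Wq"), g("Wk"), g("Wv"), g("Wo"),
                      cache$at$cache, cfg$n_heads)
  grads[[enc_par(l, "Wq")]] <- mb$dWq
  grads[[enc_par(l, "Wk")]] <- mb$dWk
  grads[[enc_par(l, "Wv")]] <- mb$dWv
  grads[[enc_par(l, "Wo")]] <- mb$dWo
  grads[[enc_par(l, "bo")]] <- mb$dbo
  list(dX = l1$dX + mb$dX, grads = grads)
}

#' Multi-head self-attention on one token sequence
#'
#' Reference single-sequence interface: projects tokens into `n_heads`
#' subspaces, runs scaled dot-product attention per head, concatenates the
#' head outputs and mixes them with an output map.
#'
#' @param x `T x d_model` matrix (tokens in rows).
#' @param Wq,Wk,Wv,Wo `d_model x d_model` projection matrices (head `h` owns
#'   rows `(h-1)*d_k + 1 .. h*d_k` of the Q/K/V projections).
#' @param bo Output bias (length `d_model`).
#' @param n_heads Number of heads (must divide `d_model`).
#' @return A `T x d_model` matrix.
#' @export
mhsa <- function(x, Wq, Wk, Wv, Wo, bo = numeric(ncol(x)), n_heads = 1) {
  check_arg(ncol(x) %% n_heads == 0, "d_model must be divisible by n_heads")
  out <- mhsa_forward(t(x), Wq, Wk, Wv, Wo, bo, n_heads, nrow(x), 1L)$out
  t(out)
}

#' Softmax classification head over all encoded tokens
#'
#' Flattens and concatenates the `T` encoded tokens of a sample into one
#' vector, maps it affinely to class logits and softmax-normalises.
#'
#' @param encoded `T x d_model` matrix of encoded tokens.
#' @param W Weight matrix (`n_classes x T*d_model`).
#' @param b Bias (length `n_classes`).
#' @return Class probability vector (sums to one).
#' @export
classify <- function(encoded, W, b = numeric(nrow(W))) {
  v <- as.vector(t(encoded)) # token-major concatenation
  check_arg(length(v) == ncol(W), "head width mismatch")
  as.vector(softmax_cols(cbind(W %*% v + b)))
}
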