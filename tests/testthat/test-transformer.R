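test_that("slice flattening builds T x d_model sequences and inverts", {
  set.seed(21)
  ev2 <- lapply(1:4, function(i) matrix(rnorm(32), 2, 16))
  seq2 <- flatten_slices(ev2)
  expect_equal(dim(seq2), c(4, 32))
  ev3 <- lapply(1:4, function(i) matrix(rnorm(48), 3, 16))
  expect_equal(dim(flatten_slices(ev3)), c(4, 48))
  # row-major flatten: un-flattening recovers the capsule matrices exactly
  for (t in 1:4) {
    expect_equal(matrix(seq2[t, ], 2, 16, byrow = TRUE), ev2[[t]])
  }
  bad <- ev2
  bad[[2]] <- matrix(0, 3, 16)
  expect_error(flatten_slices(bad), class = "eegcaps_argument_error")
})

test_that("scaled dot-product attention has the analytic degenerate cases", {
  set.seed(22)
  V <- matrix(rnorm(12), 4, 3)
  # all-equal keys: every query attends uniformly -> row mean of V
  K <- matrix(1, 4, 2)
  Q <- matrix(rnorm(8), 4, 2)
  A <- scaled_dot_attention(Q, K, V)
  for (i in 1:4) expect_equal(A[i, ], colMeans(V), tolerance = 1e-12)
  # single token: softmax over one element is 1
  expect_equal(scaled_dot_attention(Q[1, , drop = FALSE], K[1, , drop = FALSE],
                                    V[1, , drop = FALSE]),
               V[1, , drop = FALSE])
  # two tokens of width one, hand-computed softmax
  q <- matrix(c(1, 2), 2, 1)
  k <- matrix(c(3, -1), 2, 1)
  v <- matrix(c(10, 20), 2, 1)
  w11 <- exp(3) / (exp(3) + exp(-1))
  w21 <- exp(6) / (exp(6) + exp(-2))
  expect_equal(scaled_dot_attention(q, k, v, d_k = 1),
               matrix(c(w11 * 10 + (1 - w11) * 20,
                        w21 * 10 + (1 - w21) * 20), 2, 1),
               tolerance = 1e-9)
  # attention rows sum to one: uniform V recovers constant output
  expect_equal(scaled_dot_attention(Q, matrix(rnorm(8), 4, 2),
                                    matrix(1, 4, 3)),
               matrix(1, 4, 3), tolerance = 1e-12)
})

test_that("multi-head attention preserves shape and reduces to one head", {
  set.seed(23)
  d <- 8
  x <- matrix(rnorm(4 * d), 4, d)
  I <- diag(d)
  # identity projections, one head: mhsa is plain self-attention
  expect_equal(mhsa(x, I, I, I, I, n_heads = 1),
               scaled_dot_attention(x, x, x), tolerance = 1e-12)
  Wq <- matrix(rnorm(d * d, sd = 0.3), d, d)
  Wk <- matrix(rnorm(d * d, sd = 0.3), d, d)
  Wv <- matrix(rnorm(d * d, sd = 0.3), d, d)
  Wo <- matrix(rnorm(d * d, sd = 0.3), d, d)
  out <- mhsa(x, Wq, Wk, Wv, Wo, n_heads = 4)
  expect_equal(dim(out), dim(x))
})

test_that("encoder layers preserve shape and normalise tokens", {
  cfg <- encoder_config(d_model = 8, n_layers = 2, n_heads = 2,
                        ffn_hidden = 16, dropout = 0, T = 4)
  p <- eegcaps:::local_seed(31, eegcaps:::encoder_init(cfg))
  X <- matrix(rnorm(8 * 8), 8, 8) # T*B = 4*2 tokens
  st <- eegcaps:::encoder_layer_forward(X, p, 1, cfg, B = 2)
  expect_equal(dim(st$out), dim(X))
  # layer-norm internals: per-token mean 0, variance 1 before affine rescale
  xhat <- st$cache$ln2$xhat
  expect_equal(colMeans(xhat), rep(0, 8), tolerance = 1e-10)
  expect_equal(apply(xhat, 2, function(v) mean(v^2)), rep(1, 8),
               tolerance = 1e-4)
  # stacking composes
  st2 <- eegcaps:::encoder_layer_forward(st$out, p, 2, cfg, B = 2)
  expect_equal(dim(st2$out), dim(X))
})

test_that("softmax head yields proper shift-invariant probabilities", {
  set.seed(24)
  enc <- matrix(rnorm(4 * 8), 4, 8)
  W <- matrix(rnorm(2 * 32, sd = 0.2), 2, 32)
  b <- c(0.3, -0.1)
  pr <- classify(enc, W, b)
  expect_equal(sum(pr), 1)
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(classify(enc, W * 0, b * 0), c(0.5, 0.5))
  # adding a constant to all logits leaves probabilities unchanged
  expect_equal(classify(enc, W, b + 7), pr, tolerance = 1e-12)
})

test_that("token order matters exactly when positional encoding is on", {
  samples <- tiny_samples()[1:2]
  ns <- normalize_maps(samples)
  Xf <- eegcaps:::samples_to_matrix(ns)
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7) # swap slice order within samples (T = 4)
  for (pe in c("sinusoidal", "none")) {
    cfg <- model_config_small(positional_encoding = pe)
    params <- model_init(cfg, seed = 42)
    # make the head permutation-invariant: sum over token blocks
    d <- cfg$d_model
    Wblk <- matrix(rnorm(cfg$n_classes * d, sd = 0.1), cfg$n_classes, d)
    params$cls_W <- do.call(cbind, rep(list(Wblk), cfg$T))
    p1 <- eegcaps:::model_forward(params, Xf, cfg)$probs
    p2 <- eegcaps:::model_forward(params, Xf[, perm], cfg)$probs
    if (pe == "sinusoidal") {
      expect_gt(max(abs(p1 - p2)), 1e-8)
    } else {
      expect_equal(p1, p2, tolerance = 1e-10)
    }
  }
})
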