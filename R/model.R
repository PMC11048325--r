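#' Full capsule-transformer model configuration
#'
#' Bundles the intra-slice capsule encoder ([capsnet_config()]) and the
#' inter-slice temporal encoder ([encoder_config()]) with the classification
#' head. The full-size model uses 256 first-layer filters, 32 capsule channels
#' of dimension 8, 16-D class capsules, 6 encoder layers and 8 heads;
#' `model_config_small()` is a narrow preset of the same architecture for
#' quick experiments on synthetic data.
#'
#' @param n_classes 2 or 3.
#' @param T Slices per recognition-cycle sample (4).
#' @param conv_out_channels,primary_caps_channels,primary_caps_dim,emotion_caps_dim
#'   Capsule-stage widths, see [capsnet_config()].
#' @param routing_iters Dynamic-routing iterations.
#' @param eca_gamma,eca_b,se_reduction Attention-block parameters.
#' @param n_layers,n_heads,ffn_hidden,dropout,positional_encoding
#'   Temporal-encoder parameters, see [encoder_config()].
#' @param use_eca,use_se,use_transformer Ablation switches; with
#'   `use_transformer = FALSE` the softmax head reads the flattened capsule
#'   tokens directly.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_classes = 2, T = 4,
                         conv_out_channels = 256,
                         primary_caps_channels = 32, primary_caps_dim = 8,
                         emotion_caps_dim = 16, routing_iters = 3,
                         eca_gamma = 2, eca_b = 1, se_reduction = 16,
                         n_layers = 6, n_heads = 8, ffn_hidden = NULL,
                         dropout = 0.1,
                         positional_encoding = "sinusoidal",
                         use_eca = TRUE, use_se = TRUE, use_transformer = TRUE) {
  caps <- capsnet_config(n_classes = n_classes,
                         conv_out_channels = conv_out_channels,
                         primary_caps_channels = primary_caps_channels,
                         primary_caps_dim = primary_caps_dim,
                         emotion_caps_dim = emotion_caps_dim,
                         routing_iters = routing_iters,
                         eca_gamma = eca_gamma, eca_b = eca_b,
                         se_reduction = se_reduction,
                         use_eca = use_eca, use_se = use_se)
  d_model <- n_classes * emotion_caps_dim
  enc <- encoder_config(d_model = d_model, n_layers = n_layers,
                        n_heads = n_heads, ffn_hidden = ffn_hidden,
                        dropout = dropout, T = T,
                        positional_encoding = positional_encoding)
  structure(list(n_classes = as.integer(n_classes), T = as.integer(T),
                 d_model = as.integer(d_model), caps = caps, enc = enc,
                 use_transformer = isTRUE(use_transformer)),
            class = "model_config")
}

#' @rdname model_config
#' @param ... Overrides passed on to [model_config()].
#' @export
model_config_small <- function(n_classes = 2, ...) {
  model_config(n_classes = n_classes,
               conv_out_channels = 32, primary_caps_channels = 4,
               primary_caps_dim = 8, emotion_caps_dim = 16,
               se_reduction = 8, n_layers = 2, n_heads = 4,
               ffn_hidden = 64, dropout = 0, ...)
}

#' Initialise model parameters
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed; initialisation is reproducible and does not
#'   disturb the caller's RNG state.
#' @return A named list of parameter arrays.
#' @export
model_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  local_seed(seed, {
    p <- capsnet_init(cfg$caps)
    if (cfg$use_transformer) p <- c(p, encoder_init(cfg$enc))
    # near-zero head: training starts at the chance plateau (CE ~ log K)
    p$cls_W <- matrix(stats::runif(cfg$n_classes * cfg$T * cfg$d_model,
                                   -0.02, 0.02),
                      cfg$n_classes, cfg$T * cfg$d_model)
    p$cls_b <- numeric(cfg$n_classes)
    p
  })
}

# Accepts samples as produced by build_feature_maps (list of $x arrays of dim
# (3,16,18,T)) and returns the flat slice matrix (864 x T*n) plus labels.
samples_to_matrix <- function(samples) {
  check_arg(length(samples) >= 1, "no samples")
  T <- dim(samples[[1]]$x)[4]
  Xf <- vapply(samples, function(s) as.vector(s$x),
               numeric(length(samples[[1]]$x)))
  dim(Xf) <- c(prod(dim(samples[[1]]$x)[1:3]), T * length(samples))
  Xf
}

sample_classes <- function(samples) {
  y <- vapply(samples, function(s) {
    check_arg(!is.null(s$label$class), "samples must carry a 'class' label")
    as.integer(s$label$class)
  }, integer(1))
  y
}

# Forward pass on a flat slice matrix Xf (864 x T*B).
model_forward <- function(params, Xf, cfg, training = FALSE) {
  B <- ncol(Xf) %/% cfg$T
  cp <- capsnet_forward(params, Xf, cfg$caps)
  X <- cp$out # (d_model x T*B)
  enc_caches <- NULL
  if (cfg$use_transformer) {
    if (cfg$enc$positional_encoding == "sinusoidal") {
      pe <- positional_encoding_matrix(cfg$d_model, cfg$T)
      X <- X + pe[, rep(seq_len(cfg$T), B), drop = FALSE]
    }
    enc_caches <- vector("list", cfg$enc$n_layers)
    for (l in seq_len(cfg$enc$n_layers)) {
      st <- encoder_layer_forward(X, params, l, cfg$enc, B, training)
      enc_caches[[l]] <- st$cache
      X <- st$out
    }
  }
  Z <- X
  dim(Z) <- c(cfg$d_model * cfg$T, B)
  logits <- params$cls_W %*% Z + params$cls_b
  probs <- softmax_cols(logits)
  list(probs = probs, logits = logits,
       cache = list(cp = cp, enc = enc_caches, Z = Z, B = B))
}

# Cross-entropy loss and full gradient. y: integer classes 0..J-1, length B.
model_loss_grad <- function(params, Xf, y, cfg, training = TRUE) {
  fw <- model_forward(params, Xf, cfg, training)
  B <- fw$cache$B
  J <- cfg$n_classes
  iy <- cbind(as.integer(y) + 1L, seq_len(B))
  py <- fw$probs[iy]
  loss <- -mean(log(pmax(py, 1e-300)))
  dlogits <- fw$probs
  dlogits[iy] <- dlogits[iy] - 1
  dlogits <- dlogits / B
  grads <- list()
  grads$cls_W <- dlogits %*% t(fw$cache$Z)
  grads$cls_b <- rowSums(dlogits)
  dZ <- crossprod(params$cls_W, dlogits)
  dX <- dZ
  dim(dX) <- c(cfg$d_model, cfg$T * B)
  if (cfg$use_transformer) {
    for (l in rev(seq_len(cfg$enc$n_layers))) {
      lb <- encoder_layer_backward(dX, params, l, cfg$enc, fw$cache$enc[[l]])
      grads <- c(grads, lb$grads)
      dX <- lb$dX
    }
    # positional encoding is an additive constant: gradient passes through
  }
  grads <- c(grads, capsnet_backward(dX, params, cfg$caps, fw$cache$cp$cache))
  list(loss = loss, grads = grads, probs = fw$probs)
}

#' Forward-classify feature-map samples
#'
#' @param params Model parameters from [model_init()] or a training
#'   checkpoint.
#' @param samples List of feature-map samples (see [build_feature_maps()]);
#'   apply the training normalisation first.
#' @param cfg The [model_config()] the parameters were built with.
#' @return A list with `probs` (`n_samples x n_classes` matrix) and `class`
#'   (integer predictions, `0`-based).
#' @export
model_predict <- function(params, samples, cfg) {
  Xf <- samples_to_matrix(samples)
  fw <- model_forward(params, Xf, cfg, training = FALSE)
  list(probs = t(fw$probs), class = max.col(t(fw$probs)) - 1L)
}

#' First convolutional stage of the capsule encoder
#'
#' Valid (unpadded) strided 2-D convolution followed by ReLU; on the
#' 3 x 16 x 18 input with 3 x 3 kernels and stride 2 the output grid is
#' 7 x 8.
#'
#' @param x Input array `(C, H, W)`.
#' @param W Filter matrix (`filters x C*k*k`, patch columns channel-fastest).
#' @param b Filter bias (length `filters`).
#' @param stride Convolution stride.
#' @return Array `(filters, out_h, out_w)`.
#' @export
conv_relu <- function(x, W, b = numeric(nrow(W)), stride = 2) {
  d <- dim(x)
  check_arg(length(d) == 3, "x must be a C x H x W array")
  k <- sqrt(ncol(W) / d[1])
  check_arg(abs(k - round(k)) < 1e-9, "W width incompatible with input channels")
  im <- im2col_index(d, as.integer(round(k)), as.integer(stride))
  out <- relu(conv2d_forward(matrix(x, prod(d), 1), W, b, im)$out)
  array(out, c(nrow(W), im$out_h, im$out_w))
}

#' Primary capsule layer on a convolutional stack
#'
#' Applies the bank of stride-1 3 x 3 capsule convolutions (all capsule
#' channels at once), optionally the SE block on the resulting planes,
#' regroups the planes into capsule vectors and squashes each capsule.
#'
#' @param x Input array `(C, H, W)` (the attention-weighted first-stage
#'   output, `256 x 7 x 8` in the full model).
#' @param W Capsule convolution filters
#'   (`primary_caps_channels*primary_caps_dim x C*9`).
#' @param b Bias (length `nrow(W)`).
#' @param caps_dim Per-capsule dimension.
#' @param se_W1,se_W2 Optional SE block weights applied to the plane stack.
#' @return An `N x caps_dim` matrix of squashed primary capsules,
#'   `N = primary_caps_channels * out_h * out_w`.
#' @export
primary_caps <- function(x, W, b = numeric(nrow(W)), caps_dim = 8,
                         se_W1 = NULL, se_W2 = NULL) {
  d <- dim(x)
  check_arg(length(d) == 3, "x must be a C x H x W array")
  O2 <- nrow(W)
  check_arg(O2 %% caps_dim == 0, "filter count must be a multiple of caps_dim")
  im <- im2col_index(d, 3L, 1L)
  Z <- conv2d_forward(matrix(x, prod(d), 1), W, b, im)$out # (O2 x P)
  if (!is.null(se_W1)) {
    Z <- se_forward(Z, se_W1, se_W2, O2, im$n_pos, 1L)$out
  }
  pc <- O2 %/% caps_dim
  dim(Z) <- c(caps_dim, pc * im$n_pos)
  t(squash_cols(Z)$out)
}
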