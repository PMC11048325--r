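# Independent reference implementations used as oracles. These deliberately
# use plain double loops / scalar arithmetic so they share no code with the
# vectorised package implementations they check.

# Sample entropy by exhaustive template comparison (Chebyshev distance,
# self-matches excluded, same start range for lengths m and m+1).
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  count <- function(len) {
    hits <- 0L
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (i == j) next
        d <- 0
        for (k in 0:(len - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) hits <- hits + 1L
      }
    }
    hits
  }
  b <- count(m)
  a <- count(m + 1)
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# Dynamic routing as a literal transcription of the recurrence: scalar loops
# over primary capsules i, class capsules j, vector components, iterations.
routing_bruteforce <- function(primary, weights, n_out, n_iters) {
  N <- nrow(primary)
  ed <- dim(weights)[1] / n_out
  uhat <- array(0, c(N, n_out, ed))
  for (i in 1:N) {
    full <- weights[, , i] %*% primary[i, ]
    for (j in 1:n_out) uhat[i, j, ] <- full[(j - 1) * ed + 1:ed]
  }
  squash1 <- function(s) {
    n2 <- sum(s^2)
    if (n2 == 0) return(s * 0)
    (n2 / (1 + n2)) * s / sqrt(n2)
  }
  b <- matrix(0, N, n_out)
  v <- matrix(0, n_out, ed)
  for (it in 1:n_iters) {
    cc <- t(apply(b, 1, function(row) exp(row - max(row)) / sum(exp(row - max(row)))))
    for (j in 1:n_out) {
      s <- rep(0, ed)
      for (i in 1:N) s <- s + cc[i, j] * uhat[i, j, ]
      v[j, ] <- squash1(s)
    }
    if (it < n_iters) {
      for (i in 1:N) for (j in 1:n_out) b[i, j] <- b[i, j] + sum(uhat[i, j, ] * v[j, ])
    }
  }
  v
}

# A small synthetic dataset of feature-map samples, cached per session.
tiny_samples <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- generate_recording(synth_spec(n_trials = 10, trial_duration = 8,
                                           effect_size = 2, seed = 401))
      cache <<- build_feature_maps(rec, slice_plan(0.5, 4),
                                   electrode_layout("deap32"))
    }
    cache
  }
})

tiny_model_cfg <- function(...) {
  defaults <- list(n_classes = 2, T = 2, conv_out_channels = 8,
                   primary_caps_channels = 2, primary_caps_dim = 4,
                   emotion_caps_dim = 4, routing_iters = 2, se_reduction = 4,
                   n_layers = 1, n_heads = 2, ffn_hidden = 8, dropout = 0)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# One DEAP-shaped synthetic subject, cached (generation is the slow part).
tiny_deap <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_deap_like(seed = 6, effect_size = 0)
    cache
  }
})
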