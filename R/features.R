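#' Feature-extraction configuration
#'
#' Parameters of the three per-window scalar features. Sample-entropy defaults
#' follow the field standard (`m = 2`, `r = 0.2 * sd`); the differential
#' entropy log base defaults to the natural log used throughout the
#' DE-for-EEG literature.
#'
#' @param sampen_m Embedding dimension for sample entropy (>= 1).
#' @param sampen_r_factor Similarity tolerance as a multiple of the window
#'   standard deviation (> 0).
#' @param psd_reduction How the periodogram is reduced to one scalar per
#'   window: `"mean"` or `"sum"` over the positive-frequency bins.
#' @param log_base `"natural"` or `"base2"` for differential entropy.
#' @param variance_floor Lower clamp on the window variance so constant
#'   windows yield a finite (very negative) entropy instead of `-Inf`.
#' @param sampen_ceiling Finite value written into feature maps when sample
#'   entropy is undefined (no template matches at length m or m + 1).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(sampen_m = 2L, sampen_r_factor = 0.2,
                           psd_reduction = c("mean", "sum"),
                           log_base = c("natural", "base2"),
                           variance_floor = 1e-12,
                           sampen_ceiling = 5) {
  check_arg(sampen_m >= 1, "sampen_m must be >= 1")
  check_arg(sampen_r_factor > 0, "sampen_r_factor must be > 0")
  check_arg(variance_floor > 0, "variance_floor must be > 0")
  structure(list(sampen_m = as.integer(sampen_m),
                 sampen_r_factor = as.numeric(sampen_r_factor),
                 psd_reduction = match.arg(psd_reduction),
                 log_base = match.arg(log_base),
                 variance_floor = as.numeric(variance_floor),
                 sampen_ceiling = as.numeric(sampen_ceiling)),
            class = "feature_config")
}

#' Differential entropy of a window
#'
#' Under a Gaussian model of the windowed signal the differential entropy
#' reduces to `0.5 * log(2 * pi * e * sigma^2)` with `sigma^2` the unbiased
#' sample variance — a log-scale band-power surrogate. The variance is clamped
#' below by `cfg$variance_floor`.
#'
#' @param x Numeric window (length >= 2).
#' @param cfg A [feature_config()].
#' @return A scalar.
#' @export
differential_entropy <- function(x, cfg = feature_config()) {
  check_arg(length(x) >= 2, "window must have length >= 2")
  v <- max(stats::var(x), cfg$variance_floor)
  h <- 0.5 * log(2 * pi * exp(1) * v)
  if (cfg$log_base == "base2") h / log(2) else h
}

#' Sample entropy of a window
#'
#' `SampEn(m, r) = -ln(B_{m+1}(r) / B_m(r))` where `B_m(r)` is the fraction of
#' template pairs (i != j, Chebyshev distance) within tolerance
#' `r = sampen_r_factor * sd(x)`; self-matches are excluded and both template
#' lengths use the same `N - m - 1` starting points (so the ratio is a proper
#' conditional probability). Because `r` scales with the window's own sd, the
#' statistic is invariant to amplitude scaling. If either count is zero the
#' value is undefined: `NA` is returned with a warning, and map assembly
#' substitutes `cfg$sampen_ceiling`.
#'
#' @param x Numeric window of length `> sampen_m + 1`.
#' @param cfg A [feature_config()].
#' @return A scalar, or `NA_real_` when undefined.
#' @export
sample_entropy <- function(x, cfg = feature_config()) {
  m <- cfg$sampen_m
  n <- length(x)
  check_arg(n > m + 1, "window must be longer than sampen_m + 1")
  r <- cfg$sampen_r_factor * stats::sd(x)
  # Chebyshev distances between all templates, via the running max over m
  # (and m+1) lagged absolute-difference matrices
  d0 <- abs(outer(x, x, "-"))
  nt <- n - m # templates of length m and m+1 both start at 1..n-m
  dm <- d0[seq_len(nt), seq_len(nt), drop = FALSE]
  if (m > 1) {
    for (k in seq_len(m - 1)) {
      dm <- pmax(dm, d0[seq_len(nt) + k, seq_len(nt) + k, drop = FALSE])
    }
  }
  dm1 <- pmax(dm, d0[seq_len(nt) + m, seq_len(nt) + m, drop = FALSE])
  # count ordered pairs i != j (equivalently 2x the i<j count)
  bm <- sum(dm <= r) - nt
  bm1 <- sum(dm1 <= r) - nt
  if (bm == 0 || bm1 == 0) {
    warning("sample entropy undefined: no template matches within tolerance")
    return(NA_real_)
  }
  -log(bm1 / bm)
}

#' Periodogram power of a window
#'
#' Computes the periodogram `P(k) = |U(k)|^2 / N` from the DFT of the window
#' and reduces it to one scalar over the positive-frequency bins
#' (`cfg$psd_reduction`, default mean). Windows reaching this function are
#' already band-filtered, so no further frequency selection is applied.
#'
#' @param x Numeric window (length >= 2).
#' @param cfg A [feature_config()].
#' @return A scalar.
#' @export
power_spectral_density <- function(x, cfg = feature_config()) {
  check_arg(length(x) >= 2, "window must have length >= 2")
  p <- periodogram(x)
  pos <- p[seq(2, 1 + floor(length(x) / 2))]
  if (cfg$psd_reduction == "sum") sum(pos) else mean(pos)
}

#' Full periodogram `|U(k)|^2 / N` over all N DFT bins
#' @param x Numeric window.
#' @return Numeric vector of length `length(x)` (bin 1 is DC).
#' @export
periodogram <- function(x) {
  Mod(stats::fft(x))^2 / length(x)
}

# The three features of one window, NA-SampEn mapped later.
window_features <- function(x, cfg) {
  c(DE = differential_entropy(x, cfg),
    SE = suppressWarnings(sample_entropy(x, cfg)),
    PSD = power_spectral_density(x, cfg))
}

#' Extract the per-slice, per-channel, per-band feature table
#'
#' Computes DE, SampEn and PSD for every channel of every band-filtered slice.
#' The result is complete over (trial, slice, channel, band, feature).
#'
#' @param band_slices A list of band-carrying slices: either the flattened
#'   output of applying [bandpass_decompose()] to each slice, or any list of
#'   `slice` objects with a `band` field.
#' @param cfg A [feature_config()].
#' @return A `feature_table`: data frame with columns `trial`, `slice`,
#'   `channel`, `band`, `feature`, `value` (undefined SampEn kept as `NA`
#'   here; substituted at map assembly).
#' @export
extract_features <- function(band_slices, cfg = feature_config()) {
  check_arg(length(band_slices) >= 1, "no slices given")
  has_band <- vapply(band_slices, function(s) !is.null(s$band), logical(1))
  check_arg(all(has_band), "every slice must carry a band identity")
  rows <- lapply(band_slices, function(s) {
    vals <- t(apply(s$data, 1, window_features, cfg = cfg))
    data.frame(trial = s$trial, slice = s$index,
               channel = rep(rownames(s$data), each = 3),
               band = s$band,
               feature = rep(c("DE", "SE", "PSD"), times = nrow(s$data)),
               value = as.vector(t(vals)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write a feature table to a columnar text file
#' @param ft A `feature_table` from [extract_features()].
#' @param path CSV path.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  invisible(path)
}
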