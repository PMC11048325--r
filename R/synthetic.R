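#' Specification for synthetic band-structured EEG
#'
#' Describes a synthetic multichannel recording whose class label modulates
#' the amplitude of one frequency band in a chosen subset of channels. Each
#' channel is a sum of four band-limited noise components (theta, alpha, beta,
#' gamma — produced by the same order-3 Butterworth bandpass the analysis
#' pipeline uses, so generator and pipeline agree on band definitions) plus
#' white noise. For a trial of class `c > 0` the `effect_band` component in
#' `effect_channels` is scaled by `1 + c * effect_size`.
#'
#' @param n_channels 32 (DEAP-style montage) or 62 (SEED-style montage).
#' @param sampling_rate Sampling rate in Hz; must exceed 100 Hz so the
#'   31-50 Hz gamma band is representable.
#' @param n_trials Number of trials; class labels are balanced.
#' @param trial_duration Trial length in seconds.
#' @param n_classes 2 or 3.
#' @param effect_channels Channel names carrying the class effect; must belong
#'   to the montage.
#' @param effect_band One of `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @param effect_size Dimensionless multiplier on band amplitude (> 0 for an
#'   effect; 0 gives a null dataset).
#' @param noise_sd Standard deviation of the additive white noise, in the same
#'   units as the unit-variance band components.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 32, sampling_rate = 128, n_trials = 40,
                       trial_duration = 8, n_classes = 2,
                       effect_channels = c("F3", "F4", "Fz", "C3", "C4", "Cz"),
                       effect_band = "gamma", effect_size = 1,
                       noise_sd = 0.5, seed = 1L) {
  check_arg(n_channels %in% c(32, 62), "n_channels must be 32 or 62")
  check_arg(sampling_rate > 100, "sampling_rate must exceed 100 Hz")
  check_arg(n_trials >= 1, "n_trials must be >= 1")
  check_arg(trial_duration > 0, "trial_duration must be > 0")
  check_arg(n_classes %in% c(2, 3), "n_classes must be 2 or 3")
  check_arg(effect_band %in% c("theta", "alpha", "beta", "gamma"),
            "unknown effect_band")
  check_arg(effect_size >= 0, "effect_size must be >= 0")
  check_arg(noise_sd >= 0, "noise_sd must be >= 0")
  layout <- electrode_layout(if (n_channels == 32) "deap32" else "seed62")
  bad <- setdiff(effect_channels, layout$channel)
  if (length(bad)) {
    abort2(sprintf("effect channel(s) not in montage: %s", paste(bad, collapse = ", ")),
           "eegcaps_montage_error")
  }
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate = as.numeric(sampling_rate),
                 n_trials = as.integer(n_trials),
                 trial_duration = as.numeric(trial_duration),
                 n_classes = as.integer(n_classes),
                 effect_channels = as.character(effect_channels),
                 effect_band = effect_band,
                 effect_size = as.numeric(effect_size),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed),
                 layout = layout),
            class = "synth_spec")
}

#' Generate a synthetic recording with known class-conditional band structure
#'
#' @param spec A [synth_spec()].
#' @return A [new_recording()] with a `class` label column (classes
#'   `0..n_classes-1`, balanced to within one trial).
#' @examples
#' rec <- generate_recording(synth_spec(n_trials = 4, trial_duration = 2))
#' n_trials(rec)
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  bands <- band_specs()
  n_samp <- round(spec$trial_duration * spec$sampling_rate)
  channels <- spec$layout$channel[seq_len(spec$n_channels)]
  eff_idx <- match(spec$effect_channels, channels)
  eff_band_row <- match(spec$effect_band, bands$name)
  # filtfilt start-up transients are avoided by generating with padding and
  # cropping the central n_samp samples
  pad <- ceiling(spec$sampling_rate)
  local_seed(spec$seed, {
    labels <- sample(rep(seq_len(spec$n_classes) - 1L, length.out = spec$n_trials))
    signals <- lapply(seq_len(spec$n_trials), function(tr) {
      cls <- labels[tr]
      x <- matrix(0, spec$n_channels, n_samp)
      for (b in seq_len(nrow(bands))) {
        w <- matrix(rnorm(spec$n_channels * (n_samp + 2 * pad)),
                    spec$n_channels, n_samp + 2 * pad)
        comp <- bandpass_matrix(w, spec$sampling_rate,
                                bands$low[b], bands$high[b], bands$filter_order[b])
        comp <- comp / pmax(apply(comp, 1, sd), 1e-12) # unit-variance components
        amp <- rep(1, spec$n_channels)
        if (b == eff_band_row && cls > 0) {
          amp[eff_idx] <- 1 + cls * spec$effect_size
        }
        x <- x + amp * comp[, pad + seq_len(n_samp), drop = FALSE]
      }
      if (spec$noise_sd > 0) {
        x <- x + matrix(rnorm(spec$n_channels * n_samp, sd = spec$noise_sd),
                        spec$n_channels, n_samp)
      }
      rownames(x) <- channels
      x
    })
    new_recording(signals, spec$sampling_rate, channels,
                  baseline_seconds = 0,
                  labels = data.frame(class = as.integer(labels)))
  })
}

#' Generate a DEAP-shaped synthetic subject
#'
#' One subject's slice of the DEAP preprocessed layout: 40 trials of
#' 32 channels x 8064 samples at 128 Hz (63 s, of which the leading 3 s are
#' pre-trial baseline), with synthetic valence/arousal ratings drawn uniformly
#' from \[1, 9\]. Classes are not hard-coded here: they are derived downstream
#' by [apply_label_rule()], mirroring the rating->threshold label pathway.
#'
#' @param seed Integer seed.
#' @param effect_size Band-amplitude multiplier tied to the (latent) valence
#'   rating being above 5, so thresholded labels are learnable; set 0 for pure
#'   noise.
#' @return A [new_recording()] with `valence` and `arousal` label columns and
#'   `baseline_seconds = 3`.
#' @export
generate_deap_like <- function(seed = 1L, effect_size = 1) {
  base <- synth_spec(n_channels = 32, sampling_rate = 128, n_trials = 40,
                     trial_duration = 63, n_classes = 2,
                     effect_size = effect_size, seed = seed)
  rec <- generate_recording(base)
  local_seed(derive_seed(seed, "deap_ratings"), {
    # ratings consistent with the latent class: class 1 -> rating in (5,9]
    cls <- rec$labels$class
    valence <- ifelse(cls == 1, runif(40, 5 + 1e-6, 9), runif(40, 1, 5))
    arousal <- ifelse(cls == 1, runif(40, 5 + 1e-6, 9), runif(40, 1, 5))
    rec$labels <- data.frame(valence = valence, arousal = arousal)
  })
  rec$baseline_seconds <- 3
  rec
}
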