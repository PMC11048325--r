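---
title: "Capsule-transformer emotion decoding from multi-domain EEG feature maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsule-transformer emotion decoding from multi-domain EEG feature maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegcaps)
```

## The problem

Emotional state modulates the oscillatory structure of the
electroencephalogram: band power, signal regularity and their scalp topography
all carry class information. `eegcaps` implements a subject-dependent emotion
decoder built from three stages:

1. **Multi-domain feature maps.** Each non-overlapping time slice of a
   multichannel recording is band-filtered into the four canonical rhythms
   (theta 4–8 Hz, alpha 8–13 Hz, beta 13–31 Hz, gamma 31–50 Hz) and summarised
   per channel by three scalars: differential entropy (DE), sample entropy
   (SampEn) and periodogram power (PSD). Each feature is placed on an 8 × 9
   scalp grid per band, the four band grids are tiled 2 × 2 into a 16 × 18
   matrix, and the three feature matrices are stacked into one
   3 × 16 × 18 tensor per slice.
2. **Intra-slice capsule encoder.** A stride-2 valid 3 × 3 convolution (256
   filters in the full model) with ReLU, an efficient-channel-attention (ECA)
   gate, a bank of stride-1 3 × 3 capsule convolutions forming 32 channels of
   8-D primary capsules (with a squeeze-and-excitation (SE) gate on the
   convolutional planes), and dynamic routing into one 16-D class capsule per
   emotion class.
3. **Inter-slice temporal encoder.** The class capsules of T = 4 consecutive
   slices are flattened into tokens of width `n_classes * 16` and passed
   through a 6-layer, 8-head post-norm transformer encoder; a softmax head
   reads all T encoded tokens.

Everything is implemented in base-R matrix code, including the forward and
backward passes of the network; the test suite verifies every analytic
gradient against central finite differences, and dynamic routing against a
straight-line scalar-loop oracle.

## Feature definitions and their parameters

**Differential entropy.** Under a per-window Gaussian model,
`DE = 0.5 * log(2 * pi * e * sigma^2)` with `sigma^2` the unbiased window
variance: a log-scale band-power surrogate. The log base is configurable
(`feature_config(log_base=)`); the default is the natural log, the convention
of the DE-for-EEG literature. A variance floor of `1e-12` keeps constant
windows finite.

**Sample entropy.** `SampEn(m, r) = -ln(B_{m+1}/B_m)`, the negative log
conditional probability that windows matching for `m` points (Chebyshev
distance, self-matches excluded) still match at `m + 1`. The parameters are
the field-standard `m = 2`, `r = 0.2 * sd(window)`; because `r` scales with
the window sd, SampEn is amplitude-invariant. On very short or very irregular
windows the conditional probability can be undefined (zero matches); the
estimator then returns `NA` with a warning, and map assembly substitutes a
configurable finite ceiling (`sampen_ceiling`, default 5 — above any value a
64-sample window can produce) so tensors stay finite.

**Periodogram power.** `P(k) = |U(k)|^2 / N` from the window DFT, reduced to
one scalar as the mean over positive-frequency bins (sum optional). Windows
reaching this reduction are already band-filtered, so no further frequency
selection is needed; the mean over bins was chosen because the windows are
short (64–200 points) and the band is pre-isolated.

## Design choices that the architecture left open

* **Electrode grids.** The 8 × 9 cell assignments ship as plain CSV data
  (`inst/extdata/montage_*.csv`), laid out anatomically (frontal rows on top,
  left hemisphere left) for the 32-channel DEAP cap and the 62-channel SEED
  cap. They are conventions, not measurements, and are user-overridable;
  tests assert injectivity and completeness rather than specific coordinates.
  Cells without an electrode are structural zeros — no interpolation.
* **Band tile order** is fixed row-major as (theta, alpha / beta, gamma) and
  recorded in the sample metadata. Any consistent order is learnable by the
  network, so the choice affects reproducibility only.
* **Zero-phase filtering.** Band isolation uses the order-3 Butterworth
  bandpass applied forward-backward (`signal::filtfilt`), keeping the four
  band signals time-aligned within a window. The pipeline filters whole
  trials before slicing so short windows carry no filter start-up transients;
  the per-slice `bandpass_decompose()` entry point exists for interactive
  use and property tests.
* **Per-feature-channel normalisation.** DE (log scale), SampEn (order 1)
  and PSD (power units) are incommensurate, so occupied cells are z-scored
  per feature channel. Statistics are fitted on training folds only
  (`fit_map_stats()`) and applied unchanged to held-out data — the training
  harness enforces this by construction.
* **Capsule squash.** The canonical squash
  `v = (||s||^2 / (1 + ||s||^2)) s / ||s||` is used; routing runs 3
  iterations by default (configurable), couplings start uniform.
* **ECA/SE defaults.** ECA kernel size follows the adaptive odd mapping with
  gamma = 2, b = 1 (k = 5 at 256 channels); SE reduction r = 16. The SE block
  acts on the 256 convolutional planes of the primary-capsule stage before
  regrouping into capsules, since channel attention is defined on channel
  stacks, not capsule vectors.
* **Convolution padding** is valid (unpadded) everywhere; this is what makes
  the printed kernel/stride arithmetic consistent
  (16 × 18 → 7 × 8 → 5 × 6, hence 32 × 5 × 6 = 960 primary capsules).
* **Transformer details.** Post-norm residual layers (Add & Norm after each
  sublayer), FFN hidden width 4 × d_model, dropout 0.1, and a sinusoidal
  positional encoding added before the first layer (temporal order is the
  stated point of the stage; a `"none"` switch exists for ablation). The
  classifier reads the concatenation of all T encoded tokens rather than a
  pooled summary, because every slice's recoded vector feeds the decision.
* **Classifier head initialisation** is near zero, so an untrained model
  starts at the chance plateau (cross-entropy ≈ log K on balanced data) and
  optimisation trajectories are comparable across seeds.
* **Labels.** DEAP-style ratings binarise at the scale median with ties going
  low (class "high" iff rating > 5); SEED-style labels map
  {-1, 0, 1} → {negative, neutral, positive}. Folds are stratified by class
  (contiguous splitting is available for leakage-sensitivity studies).

## The synthetic generator

`generate_recording()` emulates band-limited multichannel EEG: each channel is
the sum of four unit-variance band-noise components — produced with the same
order-3 Butterworth bandpass the pipeline uses, so generator and analysis
agree exactly on band definitions — plus white noise (sd 0.5 by default). For
a trial of class `c > 0` the chosen band's amplitude in the chosen channels is
multiplied by `1 + c * effect_size`. Labels are balanced; everything is
reproducible from one integer seed, and no function disturbs the caller's RNG
state. `generate_deap_like()` produces one DEAP-shaped subject (40 trials ×
32 channels × 8064 samples at 128 Hz, leading 3 s baseline, uniform ratings
on the side of the latent class so thresholded labels remain learnable).

The generator deliberately omits eye-blink/EMG artifacts, volume conduction
and inter-subject variability. Passing tests therefore demonstrate that the
pipeline is implemented correctly and can learn class-conditional band
structure — not that real-data accuracies transfer; real DEAP/SEED runs
require the licensed downloads and full-size training.

## Problem sizes used in tests

The test and acceptance runs use scaled-down experiments chosen as the
smallest sizes that still exercise every code path: a 400-sample
(50 trials × 16 s) two-class synthetic set with a gamma-band effect of size 2
for learning checks, trained with the narrow `model_config_small()` preset
(32 first-stage filters, 4 capsule channels, 2 encoder layers, 4 heads —
the same architecture, reduced widths); the full 256-filter geometry is
verified shape-by-shape. The data-accounting checks run on a full DEAP-shaped
synthetic subject (40 × 32 × 8064 at 128 Hz), which yields exactly 4800
half-second slices and 1200 four-slice recognition samples after trimming the
3 s baseline.

## Known limitations

* SEED's published preprocessing mentions a three-slice fusion step whose
  definition is not reconstructible; the package applies the uniform
  four-slices-per-sample rule to both dataset styles.
* Subject-independent (cross-subject) evaluation is out of scope; all
  protocols here are subject-dependent.
* The grid layouts are anatomical conventions; users with exact cap
  coordinates should supply their own layout CSV.
* Training is CPU matrix code: ample for the synthetic studies here, not for
  full-size 10-fold runs over 32 subjects.

## Worked example

```{r example, eval = FALSE}
rec <- generate_recording(synth_spec(n_trials = 20, trial_duration = 8,
                                     effect_size = 2, seed = 11))
samples <- build_feature_maps(rec, slice_plan(0.5, 4),
                              electrode_layout("deap32"))
report <- run_cv(samples, model_config_small(),
                 train_config(batch_size = 32, max_epochs = 15,
                              n_folds = 2, seed = 5))
report
```
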