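cfg <- feature_config()

test_that("differential entropy matches the Gaussian closed form", {
  set.seed(101)
  x <- rnorm(1e5)
  expect_equal(differential_entropy(x, cfg), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.01)
  y <- rnorm(1e5, sd = 2)
  expect_equal(differential_entropy(y, cfg), 0.5 * log(8 * pi * exp(1)),
               tolerance = 0.01)
  # scaling law DE(a x) - DE(x) = ln|a| holds exactly for any window
  z <- rnorm(500)
  expect_equal(differential_entropy(3 * z, cfg) - differential_entropy(z, cfg),
               log(3), tolerance = 1e-9)
  # base-2 option rescales by ln 2
  cfg2 <- feature_config(log_base = "base2")
  expect_equal(differential_entropy(z, cfg2),
               differential_entropy(z, cfg) / log(2))
})

test_that("differential entropy is monotone in variance and floored", {
  set.seed(5)
  z <- rnorm(200)
  des <- vapply(c(0.5, 1, 2, 4), function(a) differential_entropy(a * z, cfg),
                numeric(1))
  expect_true(all(diff(des) > 0))
  expect_true(is.finite(differential_entropy(rep(1, 50), cfg)))
  expect_error(differential_entropy(1, cfg), class = "eegcaps_argument_error")
})

test_that("sample entropy equals the brute-force oracle", {
  x12 <- rep(c(1, 2, 3), 4)
  r <- 0.5 * sd(x12)
  expect_equal(sample_entropy(x12, feature_config(sampen_m = 2, sampen_r_factor = 0.5)),
               sampen_bruteforce(x12, 2, r), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(40)
    # short noisy windows can be undefined (both implementations agree on NA)
    expect_equal(suppressWarnings(sample_entropy(x, cfg)),
                 sampen_bruteforce(x, 2, 0.2 * sd(x)),
                 tolerance = 1e-12)
  }
})

test_that("sample entropy behaves as a regularity statistic", {
  # constant series: every template matches at both lengths
  expect_equal(sample_entropy(rep(4, 30), cfg), 0)
  set.seed(8)
  noise <- runif(500)
  sine <- sin(2 * pi * 5 * seq_len(500) / 500)
  expect_gt(sample_entropy(noise, cfg), sample_entropy(sine, cfg))
  # scale invariance: r is relative to sd
  x <- rnorm(100)
  expect_equal(sample_entropy(x, cfg), sample_entropy(17.3 * x, cfg),
               tolerance = 1e-12)
  # no matches -> NA with warning
  expect_warning(v <- sample_entropy(c(0, 1e6, 2, 1e-3, 5e5, 42, 7, 9e4, 1, 3e5),
                                     feature_config(sampen_r_factor = 1e-9)))
  expect_true(is.na(v))
})

test_that("periodogram power satisfies Parseval and analytic sinusoid mass", {
  set.seed(9)
  x <- rnorm(128)
  expect_equal(sum(periodogram(x)), sum(x^2), tolerance = 1e-9)
  expect_equal(power_spectral_density(rep(0, 64), cfg), 0)
  # amplitude-A sinusoid with integer cycles: total mass N A^2 / 2
  A <- 1.7
  n <- 64
  s <- A * sin(2 * pi * 5 * seq_len(n) / n)
  expect_equal(sum(periodogram(s)), n * A^2 / 2, tolerance = 1e-9)
  # sum reduction equals positive-bin total
  cfg_sum <- feature_config(psd_reduction = "sum")
  expect_equal(power_spectral_density(s, cfg_sum),
               sum(periodogram(s)[2:(1 + n %/% 2)]))
})

test_that("feature table is complete and order-invariant", {
  rec <- generate_recording(synth_spec(n_trials = 1, trial_duration = 0.5,
                                       seed = 14))
  sl <- slice_trials(rec, slice_plan(0.5, 1))
  bsl <- unlist(lapply(sl, bandpass_decompose), recursive = FALSE)
  ft <- extract_features(bsl, cfg)
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 32 * 4 * 3) # channels x bands x features x 1 slice
  expect_false(any(duplicated(ft[, 1:5])))
  # reversing slice processing order leaves the table content unchanged
  ft2 <- extract_features(rev(bsl), cfg)
  o <- function(d) d[order(d$band, d$channel, d$feature), ]
  expect_equal(o(as.data.frame(ft))$value, o(as.data.frame(ft2))$value)
  expect_error(extract_features(sl, cfg), class = "eegcaps_argument_error")
})

test_that("band-filtered windows concentrate PSD mass inside their band", {
  rec <- generate_recording(synth_spec(n_trials = 1, trial_duration = 4,
                                       noise_sd = 0, seed = 15))
  bd <- bandpass_decompose(rec$signals[[1]], rec$sampling_rate)
  bands <- band_specs()
  for (b in seq_len(4)) {
    x <- bd[[bands$name[b]]][1, 129:384] # interior window, 2 s
    p <- periodogram(x)
    n <- length(x)
    freq <- (seq_len(n) - 1) * rec$sampling_rate / n
    half <- freq <= rec$sampling_rate / 2
    sel <- half & freq >= bands$low[b] - 1 & freq <= bands$high[b] + 1
    expect_gt(sum(p[sel]) / sum(p[half]), 0.8)
  }
})
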