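test_that("bandpass decomposition isolates the right rhythms", {
  fs <- 128
  t <- seq_len(2 * fs) / fs
  x <- matrix(sin(2 * pi * 10 * t), 1, length(t)) # 10 Hz: alpha
  bd <- bandpass_decompose(x, fs)
  mid <- 65:192 # interior, away from filter edges
  amp <- function(b) max(abs(bd[[b]][1, mid]))
  expect_gt(amp("alpha"), 0.9)
  expect_lt(amp("gamma"), 0.05)
  # zero in, zero out
  z <- bandpass_decompose(matrix(0, 2, 256), fs)
  expect_true(all(vapply(z, function(m) all(m == 0), logical(1))))
  # filters are non-amplifying on white noise
  set.seed(3)
  w <- matrix(rnorm(1024), 1)
  bw <- bandpass_decompose(w, fs)
  expect_lt(sum(vapply(bw, function(m) sum(m^2), numeric(1))), sum(w^2))
  expect_error(bandpass_decompose(x, 60), class = "eegcaps_argument_error")
})

test_that("band tiling is a 2x2 block layout and exactly invertible", {
  mats <- list(theta = matrix(1, 8, 9), alpha = matrix(2, 8, 9),
               beta = matrix(3, 8, 9), gamma = matrix(4, 8, 9))
  tl <- tile_bands(mats)
  expect_equal(dim(tl), c(16, 18))
  expect_equal(mean(tl[1:8, 1:9]), 1)
  expect_equal(mean(tl[1:8, 10:18]), 2)
  expect_equal(mean(tl[9:16, 1:9]), 3)
  expect_equal(mean(tl[9:16, 10:18]), 4)
  # invertibility on arbitrary content
  set.seed(4)
  mats2 <- lapply(mats, function(m) matrix(rnorm(72), 8, 9))
  tl2 <- tile_bands(mats2)
  expect_identical(tl2[1:8, 1:9], mats2$theta)
  expect_identical(tl2[9:16, 10:18], mats2$gamma)
  expect_error(tile_bands(mats[1:3]), class = "eegcaps_argument_error")
})

test_that("assembled maps are 3 x 16 x 18 with shared spatial structure", {
  lay <- electrode_layout("deap32")
  rec <- generate_recording(synth_spec(n_trials = 1, trial_duration = 0.5,
                                       seed = 31))
  sl <- slice_trials(rec, slice_plan(0.5, 1))
  bsl <- unlist(lapply(sl, bandpass_decompose), recursive = FALSE)
  ft <- extract_features(bsl)
  fm <- assemble_map(ft, lay)
  expect_s3_class(fm, "feature_map")
  expect_equal(dim(fm$tensor), c(3, 16, 18))
  expect_true(all(is.finite(fm$tensor)))
  # structural zeros where no electrode sits, in all features and quadrants
  for (f in 1:3) expect_true(all(fm$tensor[f, , ][!fm$mask] == 0))
  # a channel's values sit at the same (row, col) offset in all 4 quadrants
  ch <- lay[lay$channel == "Cz", ]
  r <- ch$row + 1
  co <- ch$col + 1
  de_cz <- ft$value[ft$channel == "Cz" & ft$feature == "DE"]
  expect_equal(unname(c(fm$tensor[1, r, co], fm$tensor[1, r, co + 9],
                        fm$tensor[1, r + 8, co], fm$tensor[1, r + 8, co + 9])),
               de_cz[match(c("theta", "alpha", "beta", "gamma"),
                           ft$band[ft$channel == "Cz" & ft$feature == "DE"])])
  # zero features -> all-zero tensor
  ft0 <- ft
  ft0$value <- 0
  expect_true(all(assemble_map(ft0, lay)$tensor == 0))
  # incomplete coverage is rejected with the offending keys named
  expect_error(assemble_map(ft[ft$channel != "Cz", ], lay), "Cz")
})

test_that("undefined sample entropy is capped at the configured ceiling", {
  lay <- electrode_layout("deap32")
  rec <- generate_recording(synth_spec(n_trials = 1, trial_duration = 0.5,
                                       seed = 32))
  sl <- slice_trials(rec, slice_plan(0.5, 1))
  bsl <- unlist(lapply(sl, bandpass_decompose), recursive = FALSE)
  ft <- extract_features(bsl)
  ft$value[ft$feature == "SE"][1] <- NA
  fm <- assemble_map(ft, lay, feature_config(sampen_ceiling = 9.5))
  expect_true(all(is.finite(fm$tensor)))
  expect_true(any(fm$tensor[2, , ] == 9.5))
})

test_that("normalization zeroes occupied-cell means and is reusable", {
  samples <- tiny_samples()
  nz <- normalize_maps(samples)
  st <- attr(nz, "stats")
  mask <- attr(samples[[1]]$x, "mask")
  for (f in 1:3) {
    vals <- unlist(lapply(nz, function(s) {
      as.vector(s$x[f, , , ])[rep(mask, dim(s$x)[4])]
    }))
    expect_equal(mean(vals), 0, tolerance = 1e-10)
    expect_equal(sd(vals), 1, tolerance = 1e-10)
    # structural zeros untouched
    zer <- unlist(lapply(nz, function(s) {
      as.vector(s$x[f, , , ])[rep(!mask, dim(s$x)[4])]
    }))
    expect_true(all(zer == 0))
  }
  # identity stats leave maps unchanged; held-out application is deterministic
  ident <- list(mean = c(0, 0, 0), sd = c(1, 1, 1))
  expect_equal(normalize_maps(samples, ident)[[1]]$x, samples[[1]]$x,
               ignore_attr = TRUE)
  expect_identical(normalize_maps(samples[5], st), normalize_maps(samples[5], st))
})

test_that("the map pipeline is deterministic end to end", {
  sp <- synth_spec(n_trials = 2, trial_duration = 2, seed = 77)
  s1 <- build_feature_maps(generate_recording(sp))
  s2 <- build_feature_maps(generate_recording(sp))
  expect_identical(s1, s2)
  # manifest accounting matches floor arithmetic
  mf <- attr(s1, "manifest")
  expect_equal(mf$slices, rep(floor(2 / 0.5), 2))
  expect_equal(mf$samples, rep(1, 2))
})
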