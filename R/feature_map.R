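#' Tile four per-band 8 x 9 matrices into one 16 x 18 matrix
#'
#' 2 x 2 block arrangement, row-major in band order: top-left theta, top-right
#' alpha, bottom-left beta, bottom-right gamma. The operation is exactly
#' invertible by slicing the quadrants back out.
#'
#' @param mats Named list of four 8 x 9 matrices (`theta`, `alpha`, `beta`,
#'   `gamma`).
#' @param order Character vector of the four band names in row-major tile
#'   order.
#' @return A 16 x 18 matrix.
#' @export
tile_bands <- function(mats, order = c("theta", "alpha", "beta", "gamma")) {
  check_arg(all(order %in% names(mats)), "missing band matrix")
  check_arg(length(order) == 4, "tile order must name four bands")
  ok <- vapply(mats[order], function(m) is.matrix(m) && all(dim(m) == c(8, 9)),
               logical(1))
  check_arg(all(ok), "each band matrix must be 8 x 9")
  rbind(cbind(mats[[order[1]]], mats[[order[2]]]),
        cbind(mats[[order[3]]], mats[[order[4]]]))
}

# Linear indices into a 16 x 18 matrix for every layout channel, per band
# quadrant (band order: row-major 2 x 2 tiles).
tile_indices <- function(layout, order = c("theta", "alpha", "beta", "gamma")) {
  offs <- list(c(0L, 0L), c(0L, 9L), c(8L, 0L), c(8L, 9L))
  out <- lapply(seq_along(order), function(b) {
    r <- layout$row + 1L + offs[[b]][1]
    c <- layout$col + 1L + offs[[b]][2]
    (c - 1L) * 16L + r
  })
  names(out) <- order
  out
}

#' Assemble the 3 x 16 x 18 multi-domain feature map of one slice
#'
#' Stacks three per-feature 16 x 18 matrices — each the 2 x 2 band tiling of
#' the 8 x 9 electrode-grid mapping of that feature — along a leading axis in
#' order (DE, SE, PSD). Undefined sample-entropy values (`NA`) are replaced by
#' `cfg$sampen_ceiling` so the tensor is finite; structural zeros mark cells
#' with no electrode.
#'
#' @param features A `feature_table` (or subset) holding exactly one slice's
#'   rows, complete over channel x band x feature.
#' @param layout An [electrode_layout()].
#' @param cfg A [feature_config()] (for the SampEn ceiling).
#' @return An object of class `feature_map` with fields `tensor`
#'   (3 x 16 x 18), `feature_order`, `band_tile_order`, `slice_ref`, `label`,
#'   `mask` (16 x 18 occupancy).
#' @export
assemble_map <- function(features, layout, cfg = feature_config()) {
  ft <- as.data.frame(features)
  key <- unique(ft[, c("trial", "slice")])
  check_arg(nrow(key) == 1, "features must cover exactly one slice")
  bands <- c("theta", "alpha", "beta", "gamma")
  feats <- c("DE", "SE", "PSD")
  need <- nrow(layout) * length(bands) * length(feats)
  have <- unique(ft[, c("channel", "band", "feature")])
  if (nrow(have) < need) {
    full <- expand.grid(channel = layout$channel, band = bands, feature = feats,
                        stringsAsFactors = FALSE)
    miss <- full[!paste(full$channel, full$band, full$feature) %in%
                   paste(have$channel, have$band, have$feature), ]
    abort2(sprintf("incomplete feature coverage; missing e.g. %s",
                   paste(utils::head(paste(miss$channel, miss$band, miss$feature), 3),
                         collapse = "; ")),
           "eegcaps_argument_error")
  }
  tensor <- array(0, c(3, 16, 18))
  for (f in seq_along(feats)) {
    mats <- lapply(bands, function(b) {
      sub <- ft[ft$band == b & ft$feature == feats[f], ]
      v <- sub$value
      v[is.na(v)] <- cfg$sampen_ceiling
      names(v) <- sub$channel
      map_to_grid(v[layout$channel], layout)
    })
    names(mats) <- bands
    tensor[f, , ] <- tile_bands(mats, bands)
  }
  mask16 <- tile_bands(stats::setNames(rep(list(grid_mask(layout) * 1), 4), bands),
                       bands) > 0
  structure(list(tensor = tensor,
                 feature_order = feats,
                 band_tile_order = bands,
                 slice_ref = c(trial = key$trial, slice = key$slice),
                 label = attr(features, "label"),
                 mask = mask16),
            class = "feature_map")
}

#' Fit and apply per-feature-channel normalization of feature maps
#'
#' DE (log scale), SampEn (order-1 positive) and periodogram power (signal
#' power units) live on incommensurate scales, so occupied cells are z-scored
#' per feature channel before entering the network. Structural zeros stay
#' exactly zero. Statistics must be fitted on training data only and then
#' applied unchanged to held-out maps.
#'
#' @param maps A list of `feature_map` objects, or a list of model samples
#'   (objects with an `x` array whose first dimension indexes the three
#'   features).
#' @param stats Per-feature-channel statistics from [fit_map_stats()]; if
#'   `NULL`, fitted from `maps` (fitting set only!).
#' @return A list like `maps` with normalized tensors; the stats used are
#'   attached as attribute `"stats"`.
#' @export
normalize_maps <- function(maps, stats = NULL) {
  if (is.null(stats)) stats <- fit_map_stats(maps)
  out <- lapply(maps, function(m) {
    if (inherits(m, "feature_map")) {
      for (f in 1:3) {
        if (stats$sd[f] > 0) {
          sl <- m$tensor[f, , ]
          sl[m$mask] <- (sl[m$mask] - stats$mean[f]) / stats$sd[f]
          m$tensor[f, , ] <- sl
        }
      }
    } else {
      mask <- attr(m$x, "mask")
      for (f in 1:3) {
        if (stats$sd[f] > 0) {
          sl <- m$x[f, , , , drop = FALSE]
          occ <- rep(mask, times = dim(m$x)[4])
          sl[occ] <- (sl[occ] - stats$mean[f]) / stats$sd[f]
          m$x[f, , , ] <- sl
        }
      }
    }
    m
  })
  attr(out, "stats") <- stats
  out
}

#' @rdname normalize_maps
#' @export
fit_map_stats <- function(maps) {
  vals <- lapply(1:3, function(f) {
    unlist(lapply(maps, function(m) {
      if (inherits(m, "feature_map")) {
        m$tensor[f, , ][m$mask]
      } else {
        mask <- attr(m$x, "mask")
        as.vector(m$x[f, , , ])[rep(mask, times = dim(m$x)[4])]
      }
    }))
  })
  list(mean = vapply(vals, mean, numeric(1)),
       sd = vapply(vals, sd, numeric(1)))
}

#' Build model-ready samples from a recording
#'
#' The end-to-end feature pipeline: band-filter every trial (order-3
#' zero-phase Butterworth; filtering is done at trial level so short windows
#' carry no filter edge transients), cut the filtered signals into
#' non-overlapping windows, compute DE / SampEn / periodogram power per
#' (window, channel, band), place them on the electrode grid, tile bands, and
#' stack features into one 3 x 16 x 18 map per slice; finally group `T`
#' consecutive maps of a trial into one recognition-cycle sample.
#'
#' @param rec A `recording` (already downsampled/trimmed as desired; if
#'   `rec$baseline_seconds > 0` the baseline is trimmed here first).
#' @param plan A [slice_plan()].
#' @param layout An [electrode_layout()] covering `rec$channel_names`.
#' @param cfg A [feature_config()].
#' @return A list of samples, each `list(x, label, trial, group)` where `x` is
#'   a 3 x 16 x 18 x T array (attribute `"mask"`: 16 x 18 occupancy). The list
#'   carries attributes `manifest` (slice/sample counts per trial), `layout`,
#'   `band_tile_order`, `feature_order`.
#' @export
build_feature_maps <- function(rec, plan = slice_plan(),
                               layout = electrode_layout("deap32"),
                               cfg = feature_config()) {
  stopifnot(inherits(rec, "recording"))
  if (rec$baseline_seconds > 0) rec <- trim_baseline(rec)
  check_arg(setequal(rec$channel_names, layout$channel),
            "recording channels must match the montage")
  bands <- band_specs()
  wl <- as.integer(round(plan$window_seconds * rec$sampling_rate))
  check_arg(abs(plan$window_seconds * rec$sampling_rate - wl) < 1e-9,
            "window_seconds * sampling_rate must be an integer")
  tidx <- tile_indices(layout)
  mask16 <- tile_bands(stats::setNames(rep(list(grid_mask(layout) * 1), 4),
                                       c("theta", "alpha", "beta", "gamma"))) > 0
  ch_ord <- match(layout$channel, rec$channel_names)
  samples <- list()
  manifest <- data.frame(trial = integer(0), slices = integer(0),
                         samples = integer(0))
  for (tr in seq_along(rec$signals)) {
    x <- rec$signals[[tr]]
    n_win <- ncol(x) %/% wl
    n_grp <- n_win %/% plan$slices_per_sample
    manifest <- rbind(manifest,
                      data.frame(trial = tr, slices = n_win, samples = n_grp))
    if (n_grp == 0) next
    xb <- lapply(seq_len(nrow(bands)), function(b) {
      bandpass_matrix(x, rec$sampling_rate, bands$low[b], bands$high[b],
                      bands$filter_order[b])
    })
    # per-window maps for this trial
    maps <- vector("list", n_win)
    for (k in seq_len(n_win)) {
      tensor <- array(0, c(3, 16, 18))
      for (b in seq_len(nrow(bands))) {
        win <- xb[[b]][ch_ord, (k - 1L) * wl + seq_len(wl), drop = FALSE]
        de <- 0.5 * log(2 * pi * exp(1) *
                          pmax(apply(win, 1, stats::var), cfg$variance_floor))
        if (cfg$log_base == "base2") de <- de / log(2)
        se <- apply(win, 1, function(row) {
          v <- suppressWarnings(sample_entropy(row, cfg))
          if (is.na(v)) cfg$sampen_ceiling else v
        })
        pg <- Mod(stats::mvfft(t(win)))^2 / wl
        pos <- pg[seq(2, 1 + wl %/% 2), , drop = FALSE]
        psd <- if (cfg$psd_reduction == "sum") colSums(pos) else colMeans(pos)
        for (f in 1:3) {
          sl <- tensor[f, , ]
          sl[tidx[[b]]] <- list(de, se, psd)[[f]]
          tensor[f, , ] <- sl
        }
      }
      maps[[k]] <- tensor
    }
    for (g in seq_len(n_grp)) {
      ks <- (g - 1L) * plan$slices_per_sample + seq_len(plan$slices_per_sample)
      xarr <- array(0, c(3, 16, 18, plan$slices_per_sample))
      for (j in seq_along(ks)) xarr[, , , j] <- maps[[ks[j]]]
      attr(xarr, "mask") <- mask16
      samples[[length(samples) + 1L]] <-
        list(x = xarr, label = rec$labels[tr, , drop = FALSE],
             trial = tr, group = g)
    }
  }
  structure(samples,
            manifest = manifest,
            layout = attr(layout, "name"),
            band_tile_order = c("theta", "alpha", "beta", "gamma"),
            feature_order = c("DE", "SE", "PSD"))
}
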