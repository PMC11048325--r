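#' Canonical EEG frequency bands
#'
#' The four rhythms used throughout the pipeline: theta 4-8 Hz, alpha 8-13 Hz,
#' beta 13-31 Hz and gamma 31-50 Hz, each isolated with a Butterworth bandpass
#' of order 3.
#'
#' @param names Which bands to return (default all four, in tiling order).
#' @param filter_order Butterworth order (3).
#' @return A data frame with columns `name`, `low`, `high`, `filter_order`.
#' @export
band_specs <- function(names = c("theta", "alpha", "beta", "gamma"),
                       filter_order = 3L) {
  all <- data.frame(name = c("theta", "alpha", "beta", "gamma"),
                    low = c(4, 8, 13, 31),
                    high = c(8, 13, 31, 50),
                    stringsAsFactors = FALSE)
  check_arg(all(names %in% all$name), "unknown band name")
  out <- all[match(names, all$name), , drop = FALSE]
  out$filter_order <- as.integer(filter_order)
  rownames(out) <- NULL
  out
}

# Zero-phase Butterworth bandpass of each row of a channels x time matrix.
# Forward-backward filtering keeps the band outputs time-aligned.
bandpass_matrix <- function(x, sampling_rate, low, high, order = 3L) {
  check_arg(sampling_rate > 2 * high,
            sprintf("sampling rate %g Hz cannot represent a band up to %g Hz (Nyquist)",
                    sampling_rate, high))
  bf <- signal::butter(order, c(low, high) / (sampling_rate / 2), type = "pass")
  t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
}

#' Decompose a slice into the four frequency bands
#'
#' Applies the order-3 zero-phase Butterworth bandpass per band to every
#' channel of a slice (or any channels x time matrix), returning one filtered
#' copy per band. Zero-phase (forward-backward) filtering keeps the four band
#' outputs time-aligned within the window.
#'
#' @param slice A `slice` (from [slice_trials()]) or a channels x time matrix.
#' @param sampling_rate Sampling rate in Hz (taken from the slice if present).
#' @param bands A [band_specs()] data frame.
#' @return A named list (one entry per band) of objects of the same type as
#'   the input, each carrying a `band` field/attribute.
#' @export
bandpass_decompose <- function(slice, sampling_rate = NULL,
                               bands = band_specs()) {
  is_slice <- inherits(slice, "slice")
  x <- if (is_slice) slice$data else slice
  check_arg(is.matrix(x), "slice must be a matrix or a slice object")
  fs <- if (is_slice) slice$sampling_rate else sampling_rate
  check_arg(!is.null(fs), "sampling_rate required for a bare matrix")
  out <- lapply(seq_len(nrow(bands)), function(i) {
    y <- bandpass_matrix(x, fs, bands$low[i], bands$high[i], bands$filter_order[i])
    dimnames(y) <- dimnames(x)
    if (is_slice) {
      s <- slice
      s$data <- y
      s$band <- bands$name[i]
      s
    } else {
      attr(y, "band") <- bands$name[i]
      y
    }
  })
  names(out) <- bands$name
  out
}
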