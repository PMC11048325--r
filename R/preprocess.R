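#' Slicing plan: window length and recognition-cycle grouping
#'
#' @param window_seconds Non-overlapping window length in seconds (0.5 for
#'   DEAP-style 128 Hz data, 1.0 for SEED-style 200 Hz data).
#' @param slices_per_sample Consecutive slices grouped into one
#'   recognition-cycle sample (4).
#' @return An object of class `slice_plan`.
#' @export
slice_plan <- function(window_seconds = 0.5, slices_per_sample = 4L) {
  check_arg(window_seconds > 0, "window_seconds must be > 0")
  check_arg(slices_per_sample >= 1, "slices_per_sample must be >= 1")
  structure(list(window_seconds = as.numeric(window_seconds),
                 slices_per_sample = as.integer(slices_per_sample)),
            class = "slice_plan")
}

#' Downsample a recording
#'
#' Anti-alias filtered polyphase resampling of every channel of every trial.
#' Trial durations are preserved to within one sample.
#'
#' @param rec A `recording`.
#' @param target_rate Target sampling rate in Hz (must not exceed the current
#'   rate).
#' @return A `recording` at `target_rate`.
#' @export
downsample <- function(rec, target_rate) {
  stopifnot(inherits(rec, "recording"))
  check_arg(is.numeric(target_rate) && target_rate > 0, "target_rate must be > 0")
  check_arg(target_rate <= rec$sampling_rate,
            "target_rate must not exceed the current sampling rate")
  if (target_rate == rec$sampling_rate) return(rec)
  # rational resampling factor p/q in lowest terms
  k <- 1
  while (abs(target_rate * k - round(target_rate * k)) > 1e-9 ||
         abs(rec$sampling_rate * k - round(rec$sampling_rate * k)) > 1e-9) {
    k <- k * 10
    check_arg(k <= 1e6, "sampling rates must be rational to 6 decimals")
  }
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  p <- round(target_rate * k)
  q <- round(rec$sampling_rate * k)
  g <- gcd2(p, q)
  pq <- c(p / g, q / g)
  rec$signals <- lapply(rec$signals, function(x) {
    n_out <- floor(ncol(x) * target_rate / rec$sampling_rate)
    y <- t(apply(x, 1, function(row) signal::resample(row, pq[1], pq[2])))
    y <- y[, seq_len(min(ncol(y), n_out)), drop = FALSE]
    rownames(y) <- rownames(x)
    y
  })
  rec$sampling_rate <- as.numeric(target_rate)
  rec
}

#' Trim the pre-trial baseline
#'
#' Removes the leading `baseline_seconds` of every trial (e.g. the 3 s
#' pre-trial segment of DEAP's 63 s epochs, leaving 60 s of usable signal).
#'
#' @param rec A `recording`.
#' @return A `recording` with `baseline_seconds = 0`.
#' @export
trim_baseline <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  nb <- round(rec$baseline_seconds * rec$sampling_rate)
  if (nb == 0) return(rec)
  short <- vapply(rec$signals, ncol, integer(1)) < nb
  check_arg(!any(short), "baseline is longer than at least one trial")
  rec$signals <- lapply(rec$signals, function(x) x[, -seq_len(nb), drop = FALSE])
  rec$baseline_seconds <- 0
  rec
}

#' Cut trials into non-overlapping time slices
#'
#' Each trial is divided into `floor(trial_len / window_len)` contiguous
#' windows; trailing remainder samples are discarded (floor semantics, no
#' padding). A 60 s DEAP trial at 128 Hz with 0.5 s windows yields 120 slices,
#' i.e. 4800 slices over 40 trials.
#'
#' @param rec A `recording`.
#' @param plan A [slice_plan()].
#' @return A list of `slice` objects, each holding `trial`, `index`, `data`
#'   (channels x window matrix), `sampling_rate`, and the trial's label row.
#' @export
slice_trials <- function(rec, plan) {
  stopifnot(inherits(rec, "recording"), inherits(plan, "slice_plan"))
  wl <- plan$window_seconds * rec$sampling_rate
  check_arg(abs(wl - round(wl)) < 1e-9,
            "window_seconds * sampling_rate must be an integer")
  wl <- as.integer(round(wl))
  check_arg(any(vapply(rec$signals, ncol, integer(1)) >= wl),
            "window does not fit in any trial")
  out <- list()
  for (tr in seq_along(rec$signals)) {
    x <- rec$signals[[tr]]
    n_win <- ncol(x) %/% wl
    lab <- rec$labels[tr, , drop = FALSE]
    for (k in seq_len(n_win)) {
      d <- x[, (k - 1L) * wl + seq_len(wl), drop = FALSE]
      rownames(d) <- rec$channel_names
      out[[length(out) + 1L]] <- structure(
        list(trial = tr, index = k, data = d,
             sampling_rate = rec$sampling_rate, label = lab),
        class = "slice")
    }
  }
  check_arg(length(out) > 0, "recording produced no slices")
  out
}

#' Group consecutive slices into recognition-cycle samples
#'
#' Runs of `slices_per_sample` consecutive slices from the same trial form one
#' sample carrying the trial label; groups never span trials and leftover
#' slices at a trial's end are discarded. 4800 DEAP slices (120 per trial)
#' grouped by 4 yield 1200 samples.
#'
#' @param slices Output of [slice_trials()], ordered by (trial, index).
#' @param plan A [slice_plan()].
#' @return A list of `slice_group` objects with fields `trial`,
#'   `slice_indices`, `slices` (list of the member slices), `label`.
#' @export
group_samples <- function(slices, plan) {
  stopifnot(inherits(plan, "slice_plan"))
  check_arg(length(slices) >= 1, "no slices to group")
  trials <- vapply(slices, function(s) s$trial, numeric(1))
  idx <- vapply(slices, function(s) s$index, numeric(1))
  ord <- order(trials, idx)
  slices <- slices[ord]
  trials <- trials[ord]
  k <- plan$slices_per_sample
  out <- list()
  for (tr in unique(trials)) {
    members <- which(trials == tr)
    n_groups <- length(members) %/% k
    for (g in seq_len(n_groups)) {
      sel <- members[(g - 1L) * k + seq_len(k)]
      out[[length(out) + 1L]] <- structure(
        list(trial = tr,
             slice_indices = vapply(slices[sel], function(s) s$index, numeric(1)),
             slices = slices[sel],
             label = slices[[sel[1]]]$label),
        class = "slice_group")
    }
  }
  out
}
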