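#' Multichannel EEG recording container
#'
#' The single ingestion format of the pipeline: every source — the synthetic
#' generator, the DEAP adapter, the SEED adapter — emits a `recording`, and
#' all preprocessing operates on it. Signals are stored per trial as
#' channels x time matrices in microvolts.
#'
#' @param signals List of numeric matrices, one per trial, each
#'   `n_channels x n_samples`. All trials must share the channel count.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Character vector of 10-20 channel labels, one per row
#'   of each signal matrix; must be unique.
#' @param baseline_seconds Leading pre-trial baseline duration per trial, in
#'   seconds (trimmed by [trim_baseline()]).
#' @param labels A data frame with one row per trial. Recognised columns:
#'   `class` (integer emotion class), `valence`/`arousal` (ratings in 1..9),
#'   `session`.
#' @return An object of class `recording`.
#' @export
new_recording <- function(signals, sampling_rate, channel_names,
                          baseline_seconds = 0, labels = NULL) {
  check_arg(is.list(signals) && length(signals) >= 1, "signals must be a non-empty list")
  check_arg(all(vapply(signals, is.matrix, logical(1))), "each trial must be a matrix")
  nch <- vapply(signals, nrow, integer(1))
  check_arg(length(unique(nch)) == 1, "all trials must share the channel count")
  check_arg(is.numeric(sampling_rate) && sampling_rate > 0, "sampling_rate must be > 0")
  check_arg(length(channel_names) == nch[1], "channel_names length must match signal rows")
  check_arg(!anyDuplicated(channel_names), "channel_names must be unique")
  check_arg(baseline_seconds >= 0, "baseline_seconds must be >= 0")
  if (is.null(labels)) labels <- data.frame(row.names = seq_along(signals))
  check_arg(is.data.frame(labels) && nrow(labels) == length(signals),
            "labels must be a data frame with one row per trial")
  structure(list(signals = signals,
                 sampling_rate = as.numeric(sampling_rate),
                 channel_names = as.character(channel_names),
                 baseline_seconds = as.numeric(baseline_seconds),
                 labels = labels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  ns <- vapply(x$signals, ncol, integer(1))
  cat(sprintf("<recording> %d trial(s), %d channels @ %g Hz\n",
              length(x$signals), length(x$channel_names), x$sampling_rate))
  cat(sprintf("  samples/trial: %s; baseline: %g s\n",
              if (length(unique(ns)) == 1) as.character(ns[1])
              else paste(range(ns), collapse = "-"),
              x$baseline_seconds))
  if (ncol(x$labels)) {
    cat("  label columns:", paste(names(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of trials in a recording
#' @param rec A [new_recording()] object.
#' @export
n_trials <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  length(rec$signals)
}

#' Write / read a recording archive
#'
#' Serialises the full recording container (signals, rate, channel names,
#' baseline, trial label table) to a single-file archive.
#'
#' @param rec A `recording`.
#' @param path File path (conventionally `.rds`).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  check_arg(inherits(rec, "recording"), "file does not contain a recording")
  rec
}
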