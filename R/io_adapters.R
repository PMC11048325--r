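#' Label derivation rules
#'
#' DEAP-style ratings are binarised at the scale median: class 1 ("high")
#' iff the rating is strictly greater than the threshold (a rating of exactly
#' 5 is "low"). SEED-style categorical labels map
#' `{-1, 0, 1}` to `{negative = 0, neutral = 1, positive = 2}`.
#'
#' @param scheme `"valence_binary"`, `"arousal_binary"` or `"seed_ternary"`.
#' @param threshold Rating threshold for the binary schemes (5, must lie in
#'   `[1, 9]`).
#' @return An object of class `label_rule`.
#' @export
label_rule <- function(scheme = c("valence_binary", "arousal_binary", "seed_ternary"),
                       threshold = 5) {
  scheme <- match.arg(scheme)
  if (scheme != "seed_ternary") {
    check_arg(threshold >= 1 && threshold <= 9, "threshold must lie in [1, 9]")
  }
  structure(list(scheme = scheme, threshold = threshold), class = "label_rule")
}

#' Attach integer class labels to a recording
#'
#' @param rec A `recording` whose label table has the fields the scheme needs
#'   (`valence`/`arousal` ratings, or `seed_label` in `{-1, 0, 1}`).
#' @param rule A [label_rule()].
#' @return The recording with an integer `class` label column added.
#' @export
apply_label_rule <- function(rec, rule) {
  stopifnot(inherits(rec, "recording"), inherits(rule, "label_rule"))
  lb <- rec$labels
  cls <- switch(rule$scheme,
    valence_binary = {
      check_arg(!is.null(lb$valence), "recording has no valence ratings")
      as.integer(lb$valence > rule$threshold)
    },
    arousal_binary = {
      check_arg(!is.null(lb$arousal), "recording has no arousal ratings")
      as.integer(lb$arousal > rule$threshold)
    },
    seed_ternary = {
      check_arg(!is.null(lb$seed_label), "recording has no seed_label column")
      check_arg(all(lb$seed_label %in% c(-1, 0, 1)),
                "seed_label values must be in {-1, 0, 1}")
      as.integer(lb$seed_label + 1L)
    })
  rec$labels$class <- cls
  rec
}

deap_channel_names <- function() electrode_layout("deap32")$channel

seed_channel_names <- function() electrode_layout("seed62")$channel

#' Read a DEAP-style per-subject archive
#'
#' Reads one subject of the DEAP preprocessed layout from an RDS archive
#' holding `list(data, labels)` with `data` a `40 x channels x 8064` array
#' (the first 32 channels are EEG, in the documented DEAP order; peripheral
#' channels are dropped) and `labels` a `40 x 4` rating matrix
#' (valence, arousal, dominance, liking in `[1, 9]`). The native DEAP `.dat`
#' pickle must be converted to this archive once (e.g. with a two-line Python
#' script); [write_deap()] writes the same dialect.
#'
#' @param path Path to the RDS archive.
#' @return A `recording`: 40 trials, 32 channels at 128 Hz,
#'   `baseline_seconds = 3`, `valence`/`arousal` rating columns.
#' @export
read_deap <- function(path) {
  obj <- readRDS(path)
  fmt_err <- function(what, exp, got) {
    abort2(sprintf("DEAP archive %s: expected %s, found %s", what, exp, got),
           "eegcaps_format_error")
  }
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$labels)) {
    abort2("DEAP archive must be list(data, labels)", "eegcaps_format_error")
  }
  d <- dim(obj$data)
  if (length(d) != 3) fmt_err("data rank", "3 (trials x channels x time)", length(d))
  if (d[1] != 40) fmt_err("trial count", "40", d[1])
  if (d[2] < 32) fmt_err("channel count", ">= 32", d[2])
  if (d[3] != 8064) fmt_err("samples per trial", "8064", d[3])
  ld <- dim(obj$labels)
  if (is.null(ld) || ld[1] != 40 || ld[2] < 2) {
    fmt_err("rating table", "40 x 4", paste(ld, collapse = " x "))
  }
  chn <- deap_channel_names()
  signals <- lapply(seq_len(40), function(tr) {
    x <- matrix(obj$data[tr, seq_len(32), ], 32, 8064)
    rownames(x) <- chn
    x
  })
  new_recording(signals, 128, chn, baseline_seconds = 3,
                labels = data.frame(valence = obj$labels[, 1],
                                    arousal = obj$labels[, 2]))
}

#' Write a recording as a DEAP-style per-subject archive
#'
#' @param rec A 40-trial, 32-channel, 8064-sample `recording` with
#'   `valence`/`arousal` rating columns (e.g. from [generate_deap_like()]).
#' @param path Output RDS path.
#' @export
write_deap <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  check_arg(n_trials(rec) == 40 && length(rec$channel_names) == 32,
            "DEAP archive needs 40 trials x 32 channels")
  check_arg(all(vapply(rec$signals, ncol, integer(1)) == 8064),
            "DEAP archive needs 8064 samples per trial")
  data <- array(0, c(40, 32, 8064))
  for (tr in seq_len(40)) data[tr, , ] <- rec$signals[[tr]]
  labels <- cbind(rec$labels$valence, rec$labels$arousal,
                  rep(5, 40), rep(5, 40))
  saveRDS(list(data = data, labels = labels), path)
  invisible(path)
}

#' Read a SEED-style per-subject archive
#'
#' Reads an RDS archive holding `list(sessions)` where each session is
#' `list(data, labels, sampling_rate)`: `data` a list of 15 per-clip
#' `62 x time` matrices (clip lengths may differ; they are preserved, not
#' padded) and `labels` a 15-vector in `{-1, 0, 1}`. The native SEED `.mat`
#' files must be converted to this archive once.
#'
#' @param path Path to the RDS archive.
#' @param session Session number to read, or `NULL` (default) to merge all
#'   sessions into one recording (45 trials for 3 sessions), with a `session`
#'   label column retained.
#' @return A `recording` with a `seed_label` column (`-1/0/1`); derive
#'   classes with [apply_label_rule()].
#' @export
read_seed <- function(path, session = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$sessions)) {
    abort2("SEED archive must be list(sessions = ...)", "eegcaps_format_error")
  }
  sess_ids <- if (is.null(session)) seq_along(obj$sessions) else as.integer(session)
  chn <- seed_channel_names()
  signals <- list()
  lab <- integer(0)
  sess_col <- integer(0)
  rate <- NULL
  for (s in sess_ids) {
    ss <- obj$sessions[[s]]
    if (is.null(ss$labels)) {
      abort2(sprintf("SEED session %d has no label vector", s),
             "eegcaps_format_error")
    }
    if (length(ss$data) != length(ss$labels)) {
      abort2(sprintf("SEED session %d: %d trials but %d labels", s,
                     length(ss$data), length(ss$labels)),
             "eegcaps_format_error")
    }
    check_arg(all(ss$labels %in% c(-1, 0, 1)), "SEED labels must be in {-1,0,1}")
    if (is.null(rate)) rate <- ss$sampling_rate
    check_arg(identical(rate, ss$sampling_rate), "sessions differ in sampling rate")
    for (tr in seq_along(ss$data)) {
      x <- ss$data[[tr]]
      if (nrow(x) != 62) {
        abort2(sprintf("SEED trial has %d channels, expected 62", nrow(x)),
               "eegcaps_format_error")
      }
      rownames(x) <- chn
      signals[[length(signals) + 1L]] <- x
    }
    lab <- c(lab, as.integer(ss$labels))
    sess_col <- c(sess_col, rep(s, length(ss$labels)))
  }
  new_recording(signals, rate, chn, baseline_seconds = 0,
                labels = data.frame(seed_label = lab, session = sess_col))
}
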