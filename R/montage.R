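#' Electrode layout on the 8 x 9 topographic grid
#'
#' Loads the (row, col) grid position of every electrode of a montage on the
#' 8 x 9 scalp matrix used to build feature maps. Two layouts ship with the
#' package, `"deap32"` (the 32 EEG channels of a DEAP headcap) and `"seed62"`
#' (the 62-channel SEED cap), both laid out anatomically: frontal rows at the
#' top, left hemisphere on the left. Positions are convention, not measurement;
#' users with a different cap can point `name` at their own CSV with columns
#' `channel,row,col` (0-based rows in `0..7`, cols in `0..8`).
#'
#' @param name `"deap32"`, `"seed62"`, or a path to a layout CSV.
#' @return An object of class `electrode_layout`: a data frame with columns
#'   `channel`, `row`, `col` plus attributes `name`, `n_rows` (8), `n_cols` (9).
#' @examples
#' lay <- electrode_layout("deap32")
#' nrow(lay) # 32
#' @export
electrode_layout <- function(name = "deap32") {
  path <- if (file.exists(name)) {
    name
  } else {
    p <- system.file("extdata", paste0("montage_", name, ".csv"), package = "eegcaps")
    if (!nzchar(p)) {
      abort2(sprintf("unknown montage '%s' (no bundled layout and no such file)", name),
             "eegcaps_montage_error")
    }
    p
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_arg(all(c("channel", "row", "col") %in% names(tab)),
            "layout CSV must have columns channel,row,col")
  tab$channel <- as.character(tab$channel)
  if (anyDuplicated(tab$channel)) {
    abort2("layout has duplicated channel names", "eegcaps_montage_error")
  }
  if (anyDuplicated(tab[, c("row", "col")])) {
    abort2("layout is not injective: two channels share a grid cell",
           "eegcaps_montage_error")
  }
  if (any(tab$row < 0 | tab$row > 7 | tab$col < 0 | tab$col > 8)) {
    abort2("layout positions must satisfy 0 <= row < 8, 0 <= col < 9",
           "eegcaps_montage_error")
  }
  structure(tab,
            name = if (file.exists(name)) basename(name) else name,
            n_rows = 8L, n_cols = 9L,
            class = c("electrode_layout", "data.frame"))
}

#' Map per-channel scalars onto the 8 x 9 electrode grid
#'
#' Places one scalar per channel at that channel's grid cell; cells with no
#' electrode are structural zeros. Mapping is by channel name, so the order of
#' `values` is irrelevant.
#'
#' @param values Named numeric vector, one value per montage channel.
#' @param layout An [electrode_layout()].
#' @return An 8 x 9 numeric matrix.
#' @export
map_to_grid <- function(values, layout) {
  stopifnot(inherits(layout, "electrode_layout"))
  nm <- names(values)
  check_arg(!is.null(nm) && all(nzchar(nm)), "values must be a named vector")
  unknown <- setdiff(nm, layout$channel)
  if (length(unknown)) {
    abort2(sprintf("channel(s) not in montage '%s': %s", attr(layout, "name"),
                   paste(unknown, collapse = ", ")),
           "eegcaps_montage_error")
  }
  missing <- setdiff(layout$channel, nm)
  if (length(missing)) {
    abort2(sprintf("missing value for montage channel(s): %s",
                   paste(missing, collapse = ", ")),
           "eegcaps_montage_error")
  }
  m <- matrix(0, attr(layout, "n_rows"), attr(layout, "n_cols"))
  idx <- match(layout$channel, nm)
  m[cbind(layout$row + 1L, layout$col + 1L)] <- as.numeric(values[idx])
  m
}

# Logical 8 x 9 mask of occupied cells for a layout.
grid_mask <- function(layout) {
  m <- matrix(FALSE, attr(layout, "n_rows"), attr(layout, "n_cols"))
  m[cbind(layout$row + 1L, layout$col + 1L)] <- TRUE
  m
}
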