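# Track-table ingestion and the FRET/CFP ratio.
#
# The CSV dialect is a minimal superset of automated-tracker exports:
# header cell_id,frame,time_h,x_um,y_um,cfp,fret[,reporter]; positions and
# reporter are optional. Times are hours in the file and in memory.

REQUIRED_TRACK_COLUMNS <- c("cell_id", "frame", "time_h", "cfp", "fret")
OPTIONAL_TRACK_COLUMNS <- c("x_um", "y_um", "reporter")

#' Read a tracked single-cell table
#'
#' Reads and validates a CSV (or tab-separated) track table as exported from
#' automated cell trackers: one row per (cell, frame) with raw CFP and FRET
#' intensities. Rows are returned sorted by `(cell_id, frame)`.
#'
#' @param path Path to the file.
#' @param sep Field separator, `","` by default.
#' @return A `data.frame` of class `track_table`.
#' @section Errors: a missing required column raises a schema error naming
#'   the column; duplicated `(cell_id, frame)` pairs or non-monotone time
#'   within a cell raise validation errors citing the offending rows.
#' @export
read_tracks <- function(path, sep = ",") {
  if (!file.exists(path)) stop_cfg("track file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  validate_tracks(tab, context = path)
}

#' Validate and sort a track table
#'
#' @param tab A data frame with the track-table columns.
#' @param context Label used in error messages (e.g. a file name).
#' @return The table sorted by `(cell_id, frame)`, class `track_table`.
#' @export
validate_tracks <- function(tab, context = "track table") {
  missing_cols <- setdiff(REQUIRED_TRACK_COLUMNS, names(tab))
  if (length(missing_cols))
    stop_cfg("%s: schema error, missing required column(s): %s", context,
             paste(missing_cols, collapse = ", "))
  for (col in c("frame", "time_h", "cfp", "fret"))
    if (!is.numeric(tab[[col]]))
      stop_cfg("%s: column '%s' must be numeric", context, col)
  # store all measurements as doubles so writing and re-reading a table
  # reproduces it exactly, whatever the textual representation
  for (col in intersect(c("time_h", "x_um", "y_um", "cfp", "fret",
                          "reporter"), names(tab)))
    tab[[col]] <- as.numeric(tab[[col]])
  key <- paste(tab$cell_id, tab$frame)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))
    stop_cfg("%s: duplicated (cell_id, frame) pairs at row(s) %s", context,
             paste(utils::head(bad, 5), collapse = ", "))
  }
  tab <- tab[order(tab$cell_id, tab$frame), , drop = FALSE]
  rownames(tab) <- NULL
  for (id in unique(tab$cell_id)) {
    tt <- tab$time_h[tab$cell_id == id]
    if (any(diff(tt) <= 0))
      stop_cfg("%s: non-monotone time within cell '%s'", context, id)
  }
  class(tab) <- c("track_table", "data.frame")
  tab
}

#' Write a track table
#'
#' Writes the CSV dialect read by [read_tracks()]. Numeric content
#' round-trips bit-exactly for finite values (full precision, no rounding).
#'
#' @param tab A track table (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tab, path) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  # maximal decimal precision so read-back reproduces the doubles exactly
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert simulated traces to a track table
#'
#' Synthetic traces carry the ratio directly rather than raw channels; they
#' are exported with `cfp = 1` and `fret = ratio` so that [compute_ratio()]
#' recovers the simulated ratio unchanged.
#'
#' @param traces List of `erk_trace` objects.
#' @return A `track_table`.
#' @export
traces_to_tracks <- function(traces) {
  rows <- lapply(traces, function(tr) {
    n <- length(tr$times)
    data.frame(cell_id = tr$cell_id,
               frame = seq_len(n),
               time_h = tr$times,
               x_um = tr$x %||% rep(NA_real_, n),
               y_um = tr$y %||% rep(NA_real_, n),
               cfp = rep(1, n),
               fret = tr$ratio,
               reporter = tr$reporter %||% rep(NA_real_, n))
  })
  validate_tracks(do.call(rbind, rows), context = "traces_to_tracks")
}

#' Compute per-cell FRET/CFP ratio traces
#'
#' Splits a track table by cell and computes the ratio `fret / cfp`
#' elementwise. Timepoints with `cfp <= 0` (or missing channel values) are
#' dropped and counted; a cell whose valid timepoints number fewer than two
#' is omitted with a warning.
#'
#' @param tab A `track_table`.
#' @return A named list of `erk_trace` objects; the total number of dropped
#'   timepoints is attached as `attr(, "dropped_points")`.
#' @export
compute_ratio <- function(tab) {
  if (!inherits(tab, "track_table")) tab <- validate_tracks(tab)
  ids <- unique(tab$cell_id)
  dropped <- 0L
  omitted <- character(0)
  traces <- list()
  for (id in ids) {
    rows <- tab[tab$cell_id == id, , drop = FALSE]
    ok <- is.finite(rows$cfp) & is.finite(rows$fret) & rows$cfp > 0
    dropped <- dropped + sum(!ok)
    rows <- rows[ok, , drop = FALSE]
    if (nrow(rows) < 2L) {
      omitted <- c(omitted, id)
      next
    }
    has_rep <- "reporter" %in% names(rows) && any(is.finite(rows$reporter))
    has_xy <- all(c("x_um", "y_um") %in% names(rows)) &&
      any(is.finite(rows$x_um))
    traces[[as.character(id)]] <- new_trace(
      id, rows$time_h, rows$fret / rows$cfp,
      reporter = if (has_rep) rows$reporter else NULL,
      x = if (has_xy) rows$x_um else NULL,
      y = if (has_xy) rows$y_um else NULL)
  }
  if (length(omitted))
    warning(sprintf("omitted %d cell(s) with <2 valid timepoints: %s",
                    length(omitted),
                    paste(utils::head(omitted, 5), collapse = ", ")),
            call. = FALSE)
  attr(traces, "dropped_points") <- dropped
  traces
}

#' Drop traces shorter than a minimum observed span
#'
#' Retains traces whose observed span (last minus first time) is strictly
#' greater than `min_duration` minutes. The strict inequality follows the
#' convention that only recordings of more than 90 min enter windowed
#' analyses.
#'
#' @param traces List of `erk_trace` objects.
#' @param min_duration Minimum span in minutes (default 90).
#' @return The retained traces (possibly an empty list).
#' @export
filter_min_duration <- function(traces, min_duration = 90) {
  keep <- vapply(traces, function(tr) trace_span(tr) * 60 > min_duration,
                 logical(1))
  traces[keep]
}
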