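# Variance-based pulse-level metrics.
#
# Two complementary measures: the variance of the ratio across the cell
# population at one timepoint (instantaneous variance), and the per-cell
# variance within overlapping 50-min moving windows (moving variance). Both
# capture amplitude and number of pulses without discretizing the signal
# into counted events. Sample variance (denominator n - 1) throughout.

#' Moving-window variance and means of one trace
#'
#' Slides a centered time window of `window` minutes across the trace in
#' steps of one sampling interval (maximally overlapping). For each window
#' position the sample variance and mean of the ratio are computed, plus the
#' mean of the reporter signal when present. Windows are defined on time,
#' not frame count; partial windows at the trace edges are dropped, and
#' window positions with fewer than 3 samples inside (e.g. across gaps) are
#' skipped.
#'
#' The variance in a window is zero exactly when the signal there is
#' constant; pulses or fluctuations inside the window raise it, making it a
#' continuous per-cell measure of pulsing level.
#'
#' @param trace An `erk_trace` spanning at least one window.
#' @param window Window length in minutes (default 50).
#' @return A data frame of class `window_series` with columns
#'   `window_center_h`, `erk_moving_variance`, `erk_moving_mean`,
#'   `reporter_moving_mean` (NA when the trace has no reporter) and `n`;
#'   `cell_id` and `window_length` are attached as attributes.
#' @export
moving_variance <- function(trace, window = 50) {
  w <- window / 60
  t <- trace$times
  x <- trace$ratio
  eps <- 1e-9
  if (trace_span(trace) < w - eps)
    stop_cfg("trace '%s': span %.2f h is shorter than one %.0f-min window",
             trace$cell_id, trace_span(trace), window)
  centers <- t[t >= t[1] + w / 2 - eps & t <= t[length(t)] - w / 2 + eps]
  rows <- lapply(centers, function(ct) {
    idx <- which(abs(t - ct) <= w / 2 + eps)
    if (length(idx) < 3L) return(NULL)
    data.frame(
      window_center_h = ct,
      erk_moving_variance = stats::var(x[idx]),
      erk_moving_mean = mean(x[idx]),
      reporter_moving_mean = if (is.null(trace$reporter)) NA_real_
                             else mean(trace$reporter[idx]),
      n = length(idx))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(window_center_h = numeric(0),
                      erk_moving_variance = numeric(0),
                      erk_moving_mean = numeric(0),
                      reporter_moving_mean = numeric(0), n = integer(0))
  attr(out, "cell_id") <- trace$cell_id
  attr(out, "window_length") <- window
  class(out) <- c("window_series", "data.frame")
  out
}

#' Per-cell pulse-level score
#'
#' The time average of the moving variance over the trace: a scalar summary
#' of a cell's pulsing level that integrates both amplitude and number of
#' pulses.
#'
#' @param ws A `window_series` from [moving_variance()].
#' @return Scalar score in squared ratio units.
#' @export
pulse_level_score <- function(ws) {
  v <- ws$erk_moving_variance
  v <- v[is.finite(v)]
  if (!length(v)) stop_cfg("empty window series: no variance values")
  mean(v)
}

#' Instantaneous (cross-population) variance
#'
#' For each timepoint, the sample variance of the ratio across all cells
#' observed there. A rise signals greater population variability of ERK
#' activity at that moment — the population-level counterpart of the
#' per-cell moving variance. Timepoints observed in fewer than 2 cells are
#' omitted.
#'
#' @param traces List of `erk_trace` objects.
#' @param timepoints Optional numeric vector of times (hours) at which to
#'   report; defaults to all times observed in any trace. Times are matched
#'   to trace samples within `tol`.
#' @param tol Time-matching tolerance in hours (default 1e-6).
#' @return Data frame with columns `time_h`, `variance`, `n_cells`. Empty
#'   (with a warning) when no timepoint is shared by 2 or more cells.
#' @export
instantaneous_variance <- function(traces, timepoints = NULL, tol = 1e-6) {
  all_t <- unlist(lapply(traces, `[[`, "times"))
  all_x <- unlist(lapply(traces, `[[`, "ratio"))
  key <- round(all_t / tol) * tol
  if (!is.null(timepoints)) {
    want <- round(timepoints / tol) * tol
    sel <- key %in% want
    key <- key[sel]
    all_x <- all_x[sel]
  }
  if (length(key)) {
    grp <- factor(key)
    n <- as.integer(table(grp))
    keep <- n >= 2L
    v <- tapply(all_x, grp, stats::var)
    out <- data.frame(time_h = as.numeric(levels(grp))[keep],
                      variance = as.numeric(v)[keep],
                      n_cells = n[keep])
  } else {
    out <- data.frame(time_h = numeric(0), variance = numeric(0),
                      n_cells = integer(0))
  }
  if (!nrow(out))
    warning("no timepoint observed in 2 or more cells", call. = FALSE)
  out
}
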