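#' Construct a single-cell trace
#'
#' A trace holds one cell's time series of the FRET/CFP ratio, optionally with
#' positions and a differentiation-reporter intensity. Times are hours and must
#' be strictly increasing; at least two samples are required.
#'
#' @param cell_id Cell identifier (coerced to character).
#' @param times Numeric vector of times in hours, strictly increasing.
#' @param ratio FRET/CFP ratio, same length as `times`, non-negative.
#' @param reporter Optional reporter intensity (arbitrary units), same length.
#' @param x,y Optional positions in micrometres, same length as `times`.
#' @param ... Additional attributes stored on the object (e.g. simulation
#'   ground truth).
#' @return An object of class `erk_trace`: a list with elements `cell_id`,
#'   `times`, `ratio` and optionally `reporter`, `x`, `y`.
#' @export
new_trace <- function(cell_id, times, ratio, reporter = NULL, x = NULL,
                      y = NULL, ...) {
  times <- as.numeric(times)
  ratio <- as.numeric(ratio)
  if (length(times) < 2L)
    stop_cfg("trace '%s': need at least 2 samples, got %d", cell_id,
             length(times))
  if (length(ratio) != length(times))
    stop_cfg("trace '%s': ratio and times lengths differ", cell_id)
  if (any(diff(times) <= 0))
    stop_cfg("trace '%s': times must be strictly increasing", cell_id)
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop_cfg("trace '%s': ratio must be finite and non-negative", cell_id)
  for (nm in c("reporter", "x", "y")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != length(times))
      stop_cfg("trace '%s': '%s' length differs from times", cell_id, nm)
  }
  obj <- structure(
    list(cell_id = as.character(cell_id), times = times, ratio = ratio,
         reporter = reporter, x = x, y = y),
    class = "erk_trace")
  extra <- list(...)
  for (nm in names(extra)) attr(obj, nm) <- extra[[nm]]
  obj
}

#' @export
print.erk_trace <- function(x, ...) {
  cat(sprintf("<erk_trace '%s': %d samples, %.2f-%.2f h, ratio %.3f-%.3f%s>\n",
              x$cell_id, length(x$times), min(x$times), max(x$times),
              min(x$ratio), max(x$ratio),
              if (!is.null(x$reporter)) ", with reporter" else ""))
  invisible(x)
}

#' Observed time span of a trace
#'
#' @param trace An `erk_trace`.
#' @return Span in hours (last minus first observed time).
#' @export
trace_span <- function(trace) {
  max(trace$times) - min(trace$times)
}
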