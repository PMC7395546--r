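# Phase diagrams: the coevolution of per-cell ERK variability and
# differentiation-reporter expression, binned into a vector field with
# normalised transition probabilities.

#' Build reporter-vs-ERK trajectories
#'
#' For every cell carrying a reporter signal, computes paired moving-window
#' series of the reporter mean (x) and either the ERK moving variance or the
#' ERK moving mean (y), giving the cell's trajectory in that plane. Only
#' traces spanning strictly more than `min_duration` minutes are analysed.
#'
#' @param traces List of `erk_trace` objects with reporter signals.
#' @param window Moving-window length in minutes (default 50).
#' @param metric `"variance"` (ERK moving variance, the pulse-level axis) or
#'   `"mean"` (ERK moving mean, the basal-activity axis).
#' @param min_duration Minimum trace span in minutes (default 90).
#' @return A data frame of class `trajectory_set` with columns `cell_id`,
#'   `step`, `inv_mean` (reporter moving mean) and `erk_metric`, time-ordered
#'   within each cell; the metric kind is attached as `attr(, "metric")`.
#' @export
build_trajectories <- function(traces, window = 50,
                               metric = c("variance", "mean"),
                               min_duration = 90) {
  metric <- match.arg(metric)
  traces <- filter_min_duration(traces, min_duration)
  rows <- lapply(traces, function(tr) {
    if (is.null(tr$reporter))
      stop_cfg("trace '%s' has no reporter channel; trajectories need one",
               tr$cell_id)
    ws <- moving_variance(tr, window = window)
    if (nrow(ws) < 2L) return(NULL)
    data.frame(cell_id = tr$cell_id,
               step = seq_len(nrow(ws)),
               inv_mean = ws$reporter_moving_mean,
               erk_metric = if (metric == "variance") ws$erk_moving_variance
                            else ws$erk_moving_mean)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = character(0), step = integer(0),
                      inv_mean = numeric(0), erk_metric = numeric(0))
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  class(out) <- c("trajectory_set", "data.frame")
  out
}

#' Bin trajectory segments into a phase-diagram vector field
#'
#' The plane spanned by reporter mean (x) and the ERK metric (y) is divided
#' into a regular grid of blocks. Every consecutive-point displacement of
#' every trajectory is assigned to the block containing its start point
#' (blocks are half-open, closed at the global maximum), and the
#' displacements within a block are averaged into the block's arrow: the
#' mean direction in which cells at those values move next.
#'
#' @param trajs A `trajectory_set` from [build_trajectories()].
#' @param n_blocks Integer vector `c(nx, ny)` (a scalar is recycled);
#'   default 10 x 10.
#' @param xlim,ylim Axis ranges; default `[0, max]` of the observed values.
#' @return An object of class `phase_diagram`: list with `blocks` (data
#'   frame `ix, iy, x_mid, y_mid, dx, dy, n`), the grid `breaks_x`/
#'   `breaks_y`, the global value maxima `x_max`/`y_max` used later for
#'   normalization, `metric`, and `n_segments`.
#' @export
bin_and_average <- function(trajs, n_blocks = c(10, 10), xlim = NULL,
                            ylim = NULL) {
  if (length(n_blocks) == 1) n_blocks <- rep(n_blocks, 2)
  if (!nrow(trajs)) stop_cfg("no trajectory points to bin")
  segs <- do.call(rbind, lapply(split(trajs, trajs$cell_id), function(d) {
    d <- d[order(d$step), , drop = FALSE]
    m <- nrow(d)
    if (m < 2L) return(NULL)
    data.frame(x0 = d$inv_mean[-m], y0 = d$erk_metric[-m],
               dx = diff(d$inv_mean), dy = diff(d$erk_metric))
  }))
  if (is.null(segs) || !nrow(segs)) stop_cfg("no trajectory segments to bin")
  x_max <- max(trajs$inv_mean)
  y_max <- max(trajs$erk_metric)
  xlim <- xlim %||% c(0, x_max)
  ylim <- ylim %||% c(0, y_max)
  if (diff(xlim) <= 0 || diff(ylim) <= 0)
    stop_cfg("degenerate phase-plane extent (zero range on an axis)")
  nx <- n_blocks[1]; ny <- n_blocks[2]
  bx <- seq(xlim[1], xlim[2], length.out = nx + 1)
  by <- seq(ylim[1], ylim[2], length.out = ny + 1)
  ix <- pmin(pmax(findInterval(segs$x0, bx, rightmost.closed = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(segs$y0, by, rightmost.closed = TRUE), 1L), ny)
  inside <- segs$x0 >= xlim[1] & segs$x0 <= xlim[2] &
            segs$y0 >= ylim[1] & segs$y0 <= ylim[2]
  segs <- segs[inside, , drop = FALSE]
  ix <- ix[inside]; iy <- iy[inside]
  grp <- interaction(ix, iy, drop = TRUE)
  blocks <- data.frame(
    ix = as.integer(tapply(ix, grp, `[`, 1)),
    iy = as.integer(tapply(iy, grp, `[`, 1)),
    dx = as.numeric(tapply(segs$dx, grp, mean)),
    dy = as.numeric(tapply(segs$dy, grp, mean)),
    n = as.integer(table(grp)))
  blocks$x_mid <- (bx[blocks$ix] + bx[blocks$ix + 1]) / 2
  blocks$y_mid <- (by[blocks$iy] + by[blocks$iy + 1]) / 2
  blocks <- blocks[order(blocks$iy, blocks$ix),
                   c("ix", "iy", "x_mid", "y_mid", "dx", "dy", "n")]
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, breaks_x = bx, breaks_y = by,
                 x_max = x_max, y_max = y_max,
                 metric = attr(trajs, "metric") %||% "variance",
                 n_segments = nrow(segs)),
            class = "phase_diagram")
}

#' Normalize arrows and compute transition probabilities
#'
#' Arrow components are rescaled by the global maxima of the two axes,
#' `x' = dx / max(reporter mean)` and `y' = dy / max(ERK metric)`, which
#' normalises both axes to `[0, 1]` and makes the components comparable.
#' The transition probabilities of each block are then
#' `r_x = x' / (|x'| + |y'|)` and `r_y = y' / (|x'| + |y'|)`: `|r_x|` is the
#' probability of moving to a neighbouring reporter-level block, `|r_y|` of
#' moving to a neighbouring ERK-metric block, and the sign gives the
#' direction (negative = toward decreasing values). By construction
#' `|r_x| + |r_y| = 1` for every block with a nonzero arrow; blocks with a
#' zero arrow get `NA` probabilities.
#'
#' @param pd A `phase_diagram` from [bin_and_average()].
#' @return The diagram with block columns `xp`, `yp`, `r_x`, `r_y` added.
#' @export
normalize_and_transition <- function(pd) {
  b <- pd$blocks
  if (!nrow(b)) stop_cfg("phase diagram has no populated blocks")
  if (pd$x_max <= 0 || pd$y_max <= 0)
    stop_cfg("cannot normalize: non-positive axis maximum")
  b$xp <- b$dx / pd$x_max
  b$yp <- b$dy / pd$y_max
  s <- abs(b$xp) + abs(b$yp)
  if (all(s == 0)) stop_cfg("all phase-diagram arrows are zero")
  b$r_x <- ifelse(s > 0, b$xp / s, NA_real_)
  b$r_y <- ifelse(s > 0, b$yp / s, NA_real_)
  pd$blocks <- b
  pd
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram (%s): %d populated blocks, %d segments, grid %dx%d>\n",
              x$metric, nrow(x$blocks), x$n_segments,
              length(x$breaks_x) - 1, length(x$breaks_y) - 1))
  invisible(x)
}
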