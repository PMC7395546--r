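# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results by exhaustive enumeration, not by
# calling the package's own code paths.

# Exhaustive strict-local-maximum scan with topographic prominence: for each
# interior index higher than both neighbours, scan outwards to the nearest
# strictly higher value (or the edge) on each side and take the minima.
oracle_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  peaks <- integer(0)
  prom <- numeric(0)
  for (i in 2:(n - 1)) {
    if (!(x[i] > x[i - 1] && x[i] > x[i + 1])) next
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > x[i])
    lmin <- min(left[seq(from = if (length(higher_l)) max(higher_l) + 1 else 1,
                         to = i - 1)])
    right <- x[(i + 1):n]
    higher_r <- which(right > x[i])
    rmin <- min(right[seq_len(if (length(higher_r)) min(higher_r) - 1
                              else length(right))])
    p <- x[i] - max(lmin, rmin)
    if (p >= min_prominence) {
      peaks <- c(peaks, i)
      prom <- c(prom, p)
    }
  }
  list(peaks = peaks, prominence = prom)
}

# Naive per-window variance/mean recomputation.
oracle_window_stats <- function(times, values, centers, window_h) {
  t(vapply(centers, function(ct) {
    v <- values[abs(times - ct) <= window_h / 2 + 1e-9]
    c(var = stats::var(v), mean = mean(v), n = length(v))
  }, c(var = 0, mean = 0, n = 0)))
}

# Double-loop pair counting in [r_lo, r_hi) over all ordered pairs.
oracle_pair_count <- function(pts, r_lo, r_hi) {
  n <- nrow(pts)
  cnt <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d >= r_lo && d < r_hi) cnt <- cnt + 1L
    }
  }
  cnt
}

oracle_cross_count <- function(ref, tgt, r_lo, r_hi) {
  cnt <- 0L
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(nrow(tgt))) {
      d <- sqrt(sum((ref[i, ] - tgt[j, ])^2))
      if (d >= r_lo && d < r_hi) cnt <- cnt + 1L
    }
  }
  cnt
}

# A flat trace with raised-cosine bumps injected at known times.
make_bumpy_trace <- function(bump_times, amplitude = 0.3, duration = 0.25,
                             span_h = 12, dt_min = 5, basal = 1,
                             cell_id = "bumpy") {
  t <- seq(0, span_h, by = dt_min / 60)
  x <- rep(basal, length(t))
  for (b in bump_times) {
    d <- t - b
    inside <- abs(d) < duration / 2
    x[inside] <- x[inside] + amplitude / 2 * (1 + cos(2 * pi * d[inside] / duration))
  }
  new_trace(cell_id, t, x)
}

# Hand-built trajectory set (bypasses moving windows) for phase-diagram tests.
make_trajs <- function(..., metric = "variance") {
  cells <- list(...)
  rows <- do.call(rbind, lapply(seq_along(cells), function(i) {
    m <- cells[[i]]
    data.frame(cell_id = sprintf("c%d", i), step = seq_len(nrow(m)),
               inv_mean = m[, 1], erk_metric = m[, 2])
  }))
  attr(rows, "metric") <- metric
  class(rows) <- c("trajectory_set", "data.frame")
  rows
}

# Random-walk trajectory set confined to the unit square.
random_trajs <- function(n_cells, n_steps, seed) {
  set.seed(seed)
  cells <- lapply(seq_len(n_cells), function(i) {
    x <- cumsum(c(stats::runif(1), stats::rnorm(n_steps - 1, 0, 0.08)))
    y <- cumsum(c(stats::runif(1), stats::rnorm(n_steps - 1, 0, 0.08)))
    cbind(pmin(pmax(x, 0), 1), pmin(pmax(y, 0), 1))
  })
  do.call(make_trajs, cells)
}
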