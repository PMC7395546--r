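# Radial distribution function (RDF) analysis of marked cell positions.
#
# g(r) = N(r, dr) / N_ref(r, dr): observed ring counts over ring counts for
# randomly distributed points in the same field of interest at the same
# intensity. Under complete spatial randomness (CSR) g(r) = 1; deviations
# from a Monte Carlo CSR envelope indicate clustering/dispersion (single
# population) or grouping/segregation (two marked populations).

# Ring convention: half-open annuli [r - dr/2, r + dr/2) centred on
# r_centers = dr/2, 3dr/2, ..., i.e. breaks seq(0, r_max, by = dr).
ring_breaks <- function(r_max, dr) seq(0, r_max, by = dr)

ring_centers <- function(r_max, dr) {
  b <- ring_breaks(r_max, dr)
  (b[-1] + b[-length(b)]) / 2
}

# Total pair counts per ring within one point set; each unordered pair
# contributes twice (once around each endpoint).
ring_counts_single <- function(pts, breaks) {
  n <- nrow(pts)
  nb <- length(breaks) - 1L
  if (n < 2L) return(rep(0, nb))
  d <- stats::dist(pts)
  idx <- findInterval(d, breaks)
  2 * tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
}

# Counts of target points in rings around reference points (ordered).
ring_counts_cross <- function(ref, target, breaks) {
  nb <- length(breaks) - 1L
  if (nrow(ref) < 1L || nrow(target) < 1L) return(rep(0, nb))
  d2 <- outer(ref[, 1], target[, 1], "-")^2 +
        outer(ref[, 2], target[, 2], "-")^2
  idx <- findInterval(sqrt(d2), breaks)
  tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
}

# Monte Carlo estimate of the reference ring counts N_ref: the mean ring
# count over `n_ref` random CSR realizations (single mode replaces the whole
# pattern; cross mode keeps the reference points and randomizes the target).
reference_counts <- function(field, n_points, breaks, n_ref, ref_points = NULL) {
  acc <- 0
  for (i in seq_len(n_ref)) {
    rnd <- sample_in_field(field, n_points)
    acc <- acc + if (is.null(ref_points)) ring_counts_single(rnd, breaks)
                 else ring_counts_cross(ref_points, rnd, breaks)
  }
  acc / n_ref
}

as_points <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x_um", "y_um"), names(points))
    points <- if (length(cols) == 2) points[, cols] else points[, 1:2]
  }
  as.matrix(points)
}

rdf_result <- function(r_centers, dr, N, N_ref, mode, n_points, n_ref) {
  g <- ifelse(N_ref > 0, N / N_ref, NA_real_)
  structure(
    data.frame(r_center = r_centers, N = N, N_ref = N_ref, g = g),
    mode = mode, dr = dr, n_points = n_points, n_ref = n_ref,
    class = c("rdf_result", "data.frame"))
}

#' Radial distribution function of a point pattern
#'
#' Constructs rings of radius `r` and width `dr` around every cell and
#' counts the cells that fall inside them, then divides by the same count
#' for randomly distributed points in the field of interest (averaged over
#' `n_ref` realizations to tame the Monte Carlo noise of the denominator).
#' Radii where the reference count is zero are returned as `NA` rather than
#' divided.
#'
#' @param points Two-column matrix/data frame of positions (micrometres);
#'   at least 2 points.
#' @param field An `erk_field` delimiting the observation region.
#' @param r_max,dr Maximum radius and ring width in micrometres (defaults
#'   150 and 10; rings are half-open `[r - dr/2, r + dr/2)`).
#' @param n_ref Number of random realizations averaged into the reference
#'   count (default 20).
#' @param seed Seed for the reference realizations.
#' @param ref_counts Optional precomputed reference counts (one per ring),
#'   e.g. from a [null_envelope()] — sharing them makes observed and null
#'   curves directly comparable.
#' @return A data frame of class `rdf_result` with columns `r_center`, `N`,
#'   `N_ref`, `g`.
#' @export
rdf <- function(points, field, r_max = 150, dr = 10, n_ref = 20, seed = 1,
                ref_counts = NULL) {
  pts <- as_points(points)
  if (nrow(pts) < 2L) stop_cfg("need at least 2 points for an RDF")
  if (r_max <= 0 || dr <= 0) stop_cfg("r_max and dr must be positive")
  breaks <- ring_breaks(r_max, dr)
  N <- ring_counts_single(pts, breaks)
  if (is.null(ref_counts))
    ref_counts <- with_seed(seed,
      reference_counts(field, nrow(pts), breaks, n_ref))
  rdf_result(ring_centers(r_max, dr), dr, N, ref_counts, "single",
             nrow(pts), n_ref)
}

#' Cross-population radial distribution function
#'
#' Rings are constructed around the reference cells (e.g. high-pulsing) and
#' the cells of the target group (e.g. low-pulsing) inside them are counted;
#' the reference count randomizes the target positions at matched intensity
#' while keeping the reference cells fixed. Values below a CSR envelope
#' indicate segregation of the two populations; above, grouping.
#'
#' @param reference_points,target_points Two-column matrices/data frames of
#'   the two non-empty groups (micrometres).
#' @inheritParams rdf
#' @return A data frame of class `rdf_result` (mode `"cross"`).
#' @export
cross_rdf <- function(reference_points, target_points, field, r_max = 150,
                      dr = 10, n_ref = 20, seed = 1, ref_counts = NULL) {
  ref <- as_points(reference_points)
  tgt <- as_points(target_points)
  if (nrow(ref) < 1L || nrow(tgt) < 1L)
    stop_cfg("both point groups must be non-empty")
  breaks <- ring_breaks(r_max, dr)
  N <- ring_counts_cross(ref, tgt, breaks)
  if (is.null(ref_counts))
    ref_counts <- with_seed(seed,
      reference_counts(field, nrow(tgt), breaks, n_ref, ref_points = ref))
  rdf_result(ring_centers(r_max, dr), dr, N, ref_counts, "cross",
             nrow(tgt), n_ref)
}

#' Monte Carlo null envelope for the RDF
#'
#' Simulates `n_realizations` completely random point patterns in the field
#' (cross mode: random target positions around the fixed reference cells),
#' computes their g(r) against a shared reference count, and returns the
#' per-radius mean and 2.5/97.5 percentile bounds. Under CSR the null mean
#' is ~1 at every radius.
#'
#' @param field An `erk_field`.
#' @param n_points Number of points per realization (cross mode: target
#'   group size).
#' @param r_max,dr Ring grid (micrometres).
#' @param n_realizations Number of null realizations (default 50; >= 2).
#' @param n_ref Random realizations averaged into the shared reference
#'   count (default 20).
#' @param seed Seed; the envelope is reproducible.
#' @param ref_points Fixed reference cells; switches to cross mode.
#' @return A data frame of class `rdf_envelope` with columns `r_center`,
#'   `null_mean`, `ci_low`, `ci_high`; the shared reference counts are
#'   attached as `attr(, "ref_counts")` for reuse in [rdf()]/[cross_rdf()],
#'   and the realization matrix as `attr(, "g_null")`.
#' @export
null_envelope <- function(field, n_points, r_max = 150, dr = 10,
                          n_realizations = 50, n_ref = 20, seed = 1,
                          ref_points = NULL) {
  if (n_realizations < 2L) stop_cfg("n_realizations must be >= 2")
  if (field$area <= 0) stop_cfg("field must have positive area")
  if (!is.null(ref_points)) ref_points <- as_points(ref_points)
  breaks <- ring_breaks(r_max, dr)
  with_seed(seed, {
    ref_counts <- reference_counts(field, n_points, breaks, n_ref,
                                   ref_points = ref_points)
    g_null <- matrix(NA_real_, n_realizations, length(breaks) - 1L)
    for (i in seq_len(n_realizations)) {
      rnd <- sample_in_field(field, n_points)
      Ni <- if (is.null(ref_points)) ring_counts_single(rnd, breaks)
            else ring_counts_cross(ref_points, rnd, breaks)
      g_null[i, ] <- ifelse(ref_counts > 0, Ni / ref_counts, NA_real_)
    }
    out <- data.frame(
      r_center = ring_centers(r_max, dr),
      null_mean = colMeans(g_null),
      ci_low = apply(g_null, 2, stats::quantile, probs = 0.025, na.rm = TRUE,
                     type = 6),
      ci_high = apply(g_null, 2, stats::quantile, probs = 0.975, na.rm = TRUE,
                      type = 6))
    attr(out, "ref_counts") <- ref_counts
    attr(out, "g_null") <- g_null
    attr(out, "mode") <- if (is.null(ref_points)) "single" else "cross"
    attr(out, "n_realizations") <- n_realizations
    class(out) <- c("rdf_envelope", "data.frame")
    out
  })
}

#' Classify an RDF against its null envelope
#'
#' Single population: g above the 95% envelope means the cells are
#' clustered at that radius, below means dispersed. Cross population: g
#' below the envelope means the two populations are segregated, above
#' means grouped. Inside the envelope the pattern is consistent with
#' complete spatial randomness.
#'
#' @param rdf_res An `rdf_result`.
#' @param envelope An `rdf_envelope` on the same ring grid.
#' @param mode `"single"` or `"cross"`; defaults to the RDF's own mode.
#' @return Character vector, one classification per radius
#'   (`"clustered"`, `"dispersed"`, `"grouped"`, `"segregated"`,
#'   `"consistent_with_null"`, or `NA` where g is undefined).
#' @export
classify_rdf <- function(rdf_res, envelope, mode = NULL) {
  mode <- mode %||% attr(rdf_res, "mode")
  if (!mode %in% c("single", "cross")) stop_cfg("mode must be single or cross")
  if (nrow(rdf_res) != nrow(envelope) ||
      max(abs(rdf_res$r_center - envelope$r_center)) > 1e-9)
    stop_cfg("RDF and envelope are on different ring grids")
  g <- rdf_res$g
  above <- if (mode == "single") "clustered" else "grouped"
  below <- if (mode == "single") "dispersed" else "segregated"
  out <- rep(NA_character_, length(g))
  ok <- is.finite(g) & is.finite(envelope$ci_low) & is.finite(envelope$ci_high)
  out[ok] <- ifelse(g[ok] > envelope$ci_high[ok], above,
                    ifelse(g[ok] < envelope$ci_low[ok], below,
                           "consistent_with_null"))
  out
}
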