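#' Simulation settings for marked spatial point patterns
#'
#' Emulates maps of basal-layer cells marked by pulse class. Positions follow
#' either complete spatial randomness (`"csr"`) or a Thomas-style cluster
#' process (`"thomas_cluster"`: uniform parent points, Gaussian-displaced
#' offspring with standard deviation `cluster_sd`). Marks (`"low"` /
#' `"high"` pulse class) are assigned either independently at random or by
#' cluster membership (`"clustered_low_pulse"`): a per-cell pseudo pulse
#' frequency decreases near cluster parents, and the `prop_low` fraction of
#' cells with the lowest values is labelled `"low"` — mimicking maps of the
#' least vs. most pulsatile cells, in which low-pulsing cells form clusters
#' on the ~50 micrometre scale of epidermal proliferative units.
#'
#' @param seed Integer seed.
#' @param n_points Total number of cells (> 0).
#' @param field An [field_rect()]/[field_polygon()]/[field_mask()] object, or
#'   a length-2 numeric `c(width, height)` shorthand for a rectangle.
#' @param process `"csr"` or `"thomas_cluster"`.
#' @param parent_intensity Cluster parents per square micrometre (used by the
#'   Thomas process and the clustered mark model).
#' @param cluster_sd Gaussian cluster spread in micrometres.
#' @param mark_model `"independent"` or `"clustered_low_pulse"`.
#' @param prop_low Fraction of cells labelled `"low"`.
#' @return An object of class `spatial_sim_config`.
#' @export
spatial_sim_config <- function(seed = 1L,
                               n_points = 1400,
                               field = c(400, 400),
                               process = c("csr", "thomas_cluster"),
                               parent_intensity = 5e-05,
                               cluster_sd = 25,
                               mark_model = c("independent",
                                              "clustered_low_pulse"),
                               prop_low = 0.5) {
  process <- match.arg(process)
  mark_model <- match.arg(mark_model)
  if (is.numeric(field) && length(field) == 2)
    field <- field_rect(field[1], field[2])
  if (!inherits(field, "erk_field"))
    stop_cfg("field must be an erk_field or c(width, height)")
  if (n_points < 1) stop_cfg("n_points must be > 0")
  if (cluster_sd <= 0) stop_cfg("cluster_sd must be > 0")
  if (prop_low <= 0 || prop_low >= 1) stop_cfg("prop_low must be in (0, 1)")
  structure(
    list(seed = as.integer(seed), n_points = as.integer(n_points),
         field = field, process = process,
         parent_intensity = parent_intensity, cluster_sd = cluster_sd,
         mark_model = mark_model, prop_low = prop_low),
    class = "spatial_sim_config")
}

#' Simulate a marked point pattern
#'
#' @param config A [spatial_sim_config()].
#' @return A data frame with columns `x_um`, `y_um`, `mark` (factor
#'   `"low"`/`"high"`); the field is attached as `attr(, "field")` and the
#'   cluster parent positions (if any) as `attr(, "parents")`. Deterministic
#'   given the config seed.
#' @export
simulate_spatial_pattern <- function(config) {
  if (!inherits(config, "spatial_sim_config"))
    stop_cfg("config must be a spatial_sim_config")
  field <- config$field
  with_seed(config$seed, {
    n <- config$n_points
    n_parents <- max(1L, stats::rpois(1, config$parent_intensity * field$area))
    parents <- sample_in_field(field, n_parents)
    if (config$process == "csr") {
      pts <- sample_in_field(field, n)
    } else {
      assign_to <- sample.int(n_parents, n, replace = TRUE)
      pts <- matrix(NA_real_, n, 2)
      todo <- seq_len(n)
      while (length(todo)) {
        cand <- parents[assign_to[todo], , drop = FALSE] +
          matrix(stats::rnorm(2 * length(todo), 0, config$cluster_sd),
                 ncol = 2)
        ok <- field_contains(field, cand)
        pts[todo[ok], ] <- cand[ok, , drop = FALSE]
        todo <- todo[!ok]
      }
    }
    marks <- if (config$mark_model == "independent") {
      sample(c("low", "high"), n, replace = TRUE,
             prob = c(config$prop_low, 1 - config$prop_low))
    } else {
      # pseudo pulse frequency: depressed near cluster parents, plus jitter
      kern <- rep(0, n)
      for (j in seq_len(n_parents)) {
        d2 <- (pts[, 1] - parents[j, 1])^2 + (pts[, 2] - parents[j, 2])^2
        kern <- pmax(kern, exp(-d2 / (2 * config$cluster_sd^2)))
      }
      pseudo_freq <- 1 - kern + stats::rnorm(n, 0, 0.05)
      k_low <- round(config$prop_low * n)
      m <- rep("high", n)
      m[order(pseudo_freq)[seq_len(k_low)]] <- "low"
      m
    }
    out <- data.frame(x_um = pts[, 1], y_um = pts[, 2],
                      mark = factor(marks, levels = c("low", "high")))
    attr(out, "field") <- field
    attr(out, "parents") <- parents
    out
  })
}
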