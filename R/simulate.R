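#' Simulation settings for synthetic single-cell ERK traces
#'
#' Defines the stochastic pulse-train model used throughout the package's
#' synthetic benchmarks. Pulses occur with exponentially distributed
#' interpulse intervals (mean `1/pulse_rate` hours), each adding a symmetric
#' raised-cosine bump of full duration `pulse_duration` and height
#' `pulse_amplitude` on top of a constant basal ratio; overlapping pulses sum
#' additively. Gaussian measurement noise of standard deviation `noise_sd` is
#' added to every sample.
#'
#' Defaults mirror the experimental regime the model emulates: sampling every
#' 5 min for 24 h, mean interpulse interval 1.52 h, pulse duration 0.25 h,
#' basal ratio near 1.0--1.2 FRET/CFP, and noise of much smaller amplitude
#' than pulses.
#'
#' With `reporter_onset_model = "coupled_to_pulse_shutdown"` the pulse train
#' stops at `shutdown_time` (hours; a length-2 vector draws a per-trace
#' uniform time from that range) and a differentiation-reporter signal rises
#' thereafter as a saturating exponential ramp, emulating reporter onset
#' coincident with pulse down-regulation.
#'
#' @param seed Integer seed; every simulation is deterministic given the seed.
#' @param sampling_interval Sampling interval in minutes (> 0).
#' @param duration Total recording duration in hours (> 0).
#' @param pulse_rate Pulses per hour (>= 0); inverse of the mean interpulse
#'   interval.
#' @param pulse_duration Full pulse duration in hours; must be below the mean
#'   interpulse interval when `pulse_rate > 0`.
#' @param pulse_amplitude Pulse height in ratio units.
#' @param basal_level Basal FRET/CFP ratio.
#' @param noise_sd Measurement noise standard deviation, ratio units (>= 0).
#' @param reporter_onset_model `"none"` or `"coupled_to_pulse_shutdown"`.
#' @param shutdown_time Shutdown time in hours (scalar, or length-2 range for
#'   a uniform per-trace draw). Required when the reporter model is coupled.
#' @param reporter_max,reporter_tau,reporter_noise_sd Saturating-ramp
#'   parameters of the reporter signal: plateau level (a.u.), rise time
#'   constant (hours) and additive Gaussian noise (a.u.).
#' @return An object of class `sim_config`.
#' @seealso [simulate_trace()], [simulate_cohort()]
#' @export
sim_config <- function(seed = 1L,
                       sampling_interval = 5,
                       duration = 24,
                       pulse_rate = 1 / 1.52,
                       pulse_duration = 0.25,
                       pulse_amplitude = 0.15,
                       basal_level = 1.1,
                       noise_sd = 0.02,
                       reporter_onset_model = c("none",
                                                "coupled_to_pulse_shutdown"),
                       shutdown_time = NULL,
                       reporter_max = 100,
                       reporter_tau = 4,
                       reporter_noise_sd = 1) {
  reporter_onset_model <- match.arg(reporter_onset_model)
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop_cfg("sampling_interval must be > 0 (minutes)")
  if (!is.numeric(duration) || duration <= 0)
    stop_cfg("duration must be > 0 (hours)")
  if (!is.numeric(pulse_rate) || pulse_rate < 0)
    stop_cfg("pulse_rate must be >= 0 (pulses per hour)")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_cfg("noise_sd must be >= 0")
  if (pulse_duration <= 0)
    stop_cfg("pulse_duration must be > 0 (hours)")
  if (pulse_rate > 0 && pulse_duration >= 1 / pulse_rate)
    stop_cfg("pulse_duration (%.3g h) must be below the mean interpulse interval (%.3g h)",
             pulse_duration, 1 / pulse_rate)
  if (reporter_onset_model == "coupled_to_pulse_shutdown") {
    if (is.null(shutdown_time))
      stop_cfg("shutdown_time is required when reporter_onset_model = 'coupled_to_pulse_shutdown'")
    if (!length(shutdown_time) %in% 1:2 || any(shutdown_time < 0) ||
        any(shutdown_time > duration))
      stop_cfg("shutdown_time must be within [0, duration]")
  }
  structure(
    list(seed = as.integer(seed),
         sampling_interval = sampling_interval,
         duration = duration,
         pulse_rate = pulse_rate,
         pulse_duration = pulse_duration,
         pulse_amplitude = pulse_amplitude,
         basal_level = basal_level,
         noise_sd = noise_sd,
         reporter_onset_model = reporter_onset_model,
         shutdown_time = shutdown_time,
         reporter_max = reporter_max,
         reporter_tau = reporter_tau,
         reporter_noise_sd = reporter_noise_sd),
    class = "sim_config")
}

# Raised-cosine bump of full duration `dur` (compact support) centred at t0.
pulse_bump <- function(times, t0, dur, amp) {
  d <- times - t0
  inside <- abs(d) < dur / 2
  out <- numeric(length(times))
  out[inside] <- amp / 2 * (1 + cos(2 * pi * d[inside] / dur))
  out
}

#' Simulate one single-cell ERK trace
#'
#' Samples a trace on a uniform time grid according to a [sim_config()]:
#' pulse event times are drawn with exponential interpulse gaps at the
#' configured rate, each pulse adds a raised-cosine bump to the basal level,
#' and Gaussian noise is added. If the reporter model is coupled, pulses stop
#' at the (possibly drawn) shutdown time and the reporter rises thereafter.
#'
#' The simulated ground truth is attached to the returned trace:
#' `attr(, "pulse_events")` (true pulse peak times, hours) and
#' `attr(, "shutdown_time")` (realised shutdown, or `NULL`).
#'
#' @param config A [sim_config()].
#' @param cell_id Identifier for the generated cell.
#' @return An [new_trace()] object; identical for identical `config`.
#' @export
simulate_trace <- function(config, cell_id = "cell_1") {
  if (!inherits(config, "sim_config"))
    stop_cfg("config must be a sim_config object")
  with_seed(config$seed, {
    dt <- config$sampling_interval / 60
    times <- seq(0, config$duration, by = dt)
    shutdown <- NULL
    if (config$reporter_onset_model == "coupled_to_pulse_shutdown") {
      st <- config$shutdown_time
      shutdown <- if (length(st) == 2L) stats::runif(1, st[1], st[2]) else st
    }
    t_stop <- shutdown %||% config$duration
    events <- numeric(0)
    if (config$pulse_rate > 0) {
      t <- stats::rexp(1, config$pulse_rate)
      while (t < t_stop) {
        events <- c(events, t)
        t <- t + stats::rexp(1, config$pulse_rate)
      }
    }
    ratio <- rep(config$basal_level, length(times))
    for (e in events)
      ratio <- ratio + pulse_bump(times, e, config$pulse_duration,
                                  config$pulse_amplitude)
    if (config$noise_sd > 0)
      ratio <- ratio + stats::rnorm(length(times), 0, config$noise_sd)
    ratio <- pmax(ratio, 0)
    reporter <- NULL
    if (!is.null(shutdown)) {
      reporter <- ifelse(times < shutdown, 0,
                         config$reporter_max *
                           (1 - exp(-(times - shutdown) / config$reporter_tau)))
      if (config$reporter_noise_sd > 0)
        reporter <- reporter +
          stats::rnorm(length(times), 0, config$reporter_noise_sd)
      reporter <- pmax(reporter, 0)
    }
    new_trace(cell_id, times, ratio, reporter = reporter,
              pulse_events = events, shutdown_time = shutdown,
              config = config)
  })
}

#' Simulate a cohort of traces
#'
#' Generates `n_per_config` independent traces per configuration. Each trace
#' receives a distinct sub-seed derived deterministically from `seed` (by
#' default the first config's seed), so the whole cohort is reproducible
#' while per-trace streams are uncorrelated.
#'
#' @param configs A [sim_config()] or a (optionally named) list of them.
#' @param n_per_config Number of traces per configuration (>= 1).
#' @param seed Master seed for sub-seed derivation; defaults to the first
#'   config's seed.
#' @return A list of `erk_trace` objects; each carries its cohort label in
#'   `attr(, "label")`.
#' @export
simulate_cohort <- function(configs, n_per_config = 1, seed = NULL) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  if (!is.list(configs) || length(configs) == 0L)
    stop_cfg("configs must be a non-empty list of sim_config objects")
  if (n_per_config < 1) stop_cfg("n_per_config must be >= 1")
  labels <- names(configs) %||% paste0("config_", seq_along(configs))
  labels[labels == ""] <- paste0("config_", which(labels == ""))
  master <- seed %||% configs[[1]]$seed
  out <- vector("list", length(configs) * n_per_config)
  k <- 0L
  for (j in seq_along(configs)) {
    cfg <- configs[[j]]
    if (!inherits(cfg, "sim_config"))
      stop_cfg("configs[[%d]] is not a sim_config", j)
    for (i in seq_len(n_per_config)) {
      k <- k + 1L
      cfg_i <- cfg
      cfg_i$seed <- derive_subseed(master, k)
      tr <- simulate_trace(cfg_i, cell_id = sprintf("%s_%04d", labels[j], i))
      attr(tr, "label") <- labels[j]
      out[[k]] <- tr
    }
  }
  names(out) <- vapply(out, function(tr) tr$cell_id, character(1))
  out
}
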