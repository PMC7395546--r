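test_that("a constant trace has no pulses and zero frequency", {
  t <- seq(0, 6, by = 5 / 60)
  ps <- detect_pulses(new_trace("flat", t, rep(1.1, length(t))))
  expect_equal(ps$n_peaks, 0)
  expect_equal(ps$frequency, 0)
  expect_length(interpulse_intervals(ps), 0)
})

test_that("injected bumps are recovered at their times with correct intervals", {
  tr <- make_bumpy_trace(c(2, 6, 10))
  ps <- detect_pulses(tr, min_prominence = 0.1)
  expect_equal(ps$peak_times, c(2, 6, 10))
  expect_equal(interpulse_intervals(ps), c(4, 4))
  expect_equal(ps$frequency, 3 / 12)
  # amplitude ~ smoothed prominence, duration ~ the injected 0.25 h
  expect_true(all(ps$durations > 0.1 & ps$durations < 0.5))
})

test_that("detection matches the brute-force local-maximum oracle", {
  set.seed(99)
  n_checked <- 0
  for (rep in 1:200) {
    n <- sample(10:50, 1)
    t <- seq(0, by = 5 / 60, length.out = n)
    x <- 1 + cumsum(stats::rnorm(n, 0, 0.05))
    x <- x - min(x) + 0.5
    mp <- stats::runif(1, 0.01, 0.2)
    tr <- new_trace(sprintf("r%d", rep), t, x)
    got <- detect_pulses(tr, smoothing_window = 0, min_prominence = mp,
                         min_separation = 0)
    want <- oracle_peaks(x, min_prominence = mp)
    expect_identical(which(t %in% got$peak_times), want$peaks)
    expect_equal(got$amplitudes, want$prominence, tolerance = 1e-12)
    n_checked <- n_checked + length(want$peaks)
  }
  expect_gt(n_checked, 100)   # the comparison actually exercised peaks
})

test_that("raising the prominence threshold never increases the peak count", {
  set.seed(7)
  for (rep in 1:20) {
    t <- seq(0, 12, by = 5 / 60)
    x <- 1 + cumsum(stats::rnorm(length(t), 0, 0.03))
    x <- x - min(x) + 0.5
    tr <- new_trace("mono", t, x)
    counts <- vapply(c(0.01, 0.03, 0.06, 0.1, 0.2), function(mp)
      detect_pulses(tr, min_prominence = mp)$n_peaks, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("min_separation enforces a dead time between kept peaks", {
  tr <- make_bumpy_trace(c(2, 2.3, 6), amplitude = 0.3)
  ps <- detect_pulses(tr, min_prominence = 0.05, min_separation = 30)
  expect_true(all(diff(ps$peak_times) >= 0.5))
})

test_that("a pulse-free negative-control cohort shows almost no pulses", {
  co <- simulate_cohort(sim_config(seed = 31, pulse_rate = 0,
                                   noise_sd = 0.01), n_per_config = 30)
  freq <- vapply(co, function(tr) detect_pulses(tr)$frequency, numeric(1))
  expect_lt(mean(freq), 0.05)
})

test_that("non-uniform sampling is resampled with a warning", {
  t <- c(seq(0, 2, by = 5 / 60), seq(2.25, 4, by = 15 / 60))
  x <- 1 + 0.3 * exp(-((t - 1.5)^2) / 0.01)
  tr <- new_trace("mixed", t, x)
  expect_warning(ps <- detect_pulses(tr, min_prominence = 0.1),
                 "non-uniform")
  expect_equal(ps$n_peaks, 1)
  expect_lt(abs(ps$peak_times - 1.5), 0.1)
})

test_that("exponential fits recover the rate and flag non-exponential data", {
  # constant intervals: MLE mean 2 h, KS strongly rejects
  fit <- fit_exponential(rep(2, 20))
  expect_equal(fit$mean_interval, 2)
  expect_equal(fit$rate, 0.5)
  expect_lt(fit$ks_p, 0.01)
  # simulated exponential: mean lands in the CLT band in >= 95% of runs
  hits <- 0L
  for (s in 1:40) {
    set.seed(1000 + s)
    f <- fit_exponential(stats::rexp(1000, rate = 1 / 1.5))
    if (f$mean_interval >= 1.38 && f$mean_interval <= 1.62) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
  # insufficient data
  expect_error(fit_exponential(rep(1, 5)), "insufficient")
})

test_that("pulse-class and basal gates apply the documented thresholds", {
  expect_equal(classify_pulse_class(c(1.4, 1.6, 0, 1.5)),
               c("low", "high", "low", "high"))
  expect_error(classify_pulse_class(-0.1), "frequency")
  expect_equal(gate_basal(c(1.25, 1.15, 1.2)), c("high", "low", "high"))
  expect_error(gate_basal(0), "positive")
})

test_that("calibrated rate estimation recovers generator rates", {
  cal <- calibrate_detection(rates = c(0.5, 1, 1.5, 2),
                             detect_params = list(min_prominence = 0.05),
                             n_traces = 20, seed = 2)
  expect_true(all(diff(cal$detected_freq) >= 0))
  co <- simulate_cohort(sim_config(seed = 888, pulse_rate = 1),
                        n_per_config = 30)
  ps <- lapply(co, detect_pulses, min_prominence = 0.05)
  f_obs <- sum(vapply(ps, `[[`, numeric(1), "n_peaks")) /
    sum(vapply(ps, `[[`, numeric(1), "span"))
  est <- estimate_rate_from_frequency(f_obs, cal)
  expect_lt(abs(est - 1), 0.2)
})
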