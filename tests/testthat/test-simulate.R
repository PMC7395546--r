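test_that("a pulse-free, noise-free config yields a constant basal trace", {
  tr <- simulate_trace(sim_config(seed = 1, pulse_rate = 0, noise_sd = 0,
                                  basal_level = 1.0))
  expect_true(all(tr$ratio == 1.0))
  expect_equal(length(tr$times), 24 * 12 + 1)
  expect_identical(attr(tr, "pulse_events"), numeric(0))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42)
  expect_identical(simulate_trace(cfg)$ratio, simulate_trace(cfg)$ratio)
  co1 <- simulate_cohort(cfg, n_per_config = 4)
  co2 <- simulate_cohort(cfg, n_per_config = 4)
  expect_identical(lapply(co1, `[[`, "ratio"), lapply(co2, `[[`, "ratio"))
  # distinct sub-seeds give distinct traces
  expect_false(identical(co1[[1]]$ratio, co1[[2]]$ratio))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(sampling_interval = 0), "sampling_interval")
  expect_error(sim_config(pulse_rate = -1), "pulse_rate")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  # pulse duration must fit below the mean interpulse interval
  expect_error(sim_config(pulse_rate = 5, pulse_duration = 0.25),
               "interpulse")
  expect_error(sim_config(reporter_onset_model = "coupled_to_pulse_shutdown"),
               "shutdown_time")
})

test_that("cohort bookkeeping preserves counts and labels", {
  cfgs <- list(a = sim_config(seed = 1, pulse_rate = 1),
               b = sim_config(seed = 2, pulse_rate = 0))
  co <- simulate_cohort(cfgs, n_per_config = 3)
  expect_length(co, 6)
  expect_equal(as.vector(table(vapply(co, attr, character(1), "label"))),
               c(3L, 3L))
  expect_error(simulate_cohort(list()), "non-empty")
})

test_that("generated interpulse intervals are exponential at the configured rate", {
  # per-trace KS test at the configured rate over 100 seeded runs
  pass <- 0L
  tot <- 0L
  for (s in 1:100) {
    tr <- simulate_trace(sim_config(seed = s))
    iv <- diff(attr(tr, "pulse_events"))
    if (length(iv) < 5) next
    tot <- tot + 1L
    p <- suppressWarnings(stats::ks.test(iv, "pexp", rate = 1 / 1.52))$p.value
    if (p > 0.01) pass <- pass + 1L
  }
  expect_gte(pass / tot, 0.95)
})

test_that("pooled interval mean matches the configured 1.52 h within 5%", {
  # long traces keep finite-window censoring of complete intervals small
  co <- simulate_cohort(sim_config(seed = 77, duration = 96),
                        n_per_config = 80)
  iv <- unlist(lapply(co, function(tr) diff(attr(tr, "pulse_events"))))
  expect_gt(length(iv), 4000)
  expect_lt(abs(mean(iv) - 1.52) / 1.52, 0.05)
})

test_that("pulse counts converge to the configured rate", {
  for (rate in c(0.658, 2)) {
    co <- simulate_cohort(sim_config(seed = 5 + round(10 * rate),
                                     pulse_rate = rate, duration = 24),
                          n_per_config = 120)
    n_events <- sum(vapply(co, function(tr)
      length(attr(tr, "pulse_events")), numeric(1)))
    emp <- n_events / (120 * 24)
    expect_lt(abs(emp - rate) / rate, 0.10)
  }
})

test_that("reporter onset is coupled to pulse shutdown", {
  cfg <- sim_config(seed = 9, reporter_onset_model = "coupled_to_pulse_shutdown",
                    shutdown_time = 10, noise_sd = 0,
                    reporter_noise_sd = 0)
  tr <- simulate_trace(cfg)
  ev <- attr(tr, "pulse_events")
  expect_true(all(ev < 10))
  expect_true(all(tr$reporter[tr$times < 10] == 0))
  post <- tr$reporter[tr$times > 10.5]
  expect_true(all(diff(post) > 0))        # saturating rise
  expect_lt(max(tr$reporter), 100)
})
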