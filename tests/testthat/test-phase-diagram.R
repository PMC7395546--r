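test_that("trajectories require a reporter and more than 90 min of data", {
  t95 <- seq(0, 95 / 60, by = 5 / 60)
  t90 <- seq(0, 90 / 60, by = 5 / 60)
  mk <- function(t, id) new_trace(id, t, rep(1, length(t)),
                                  reporter = seq_along(t))
  trajs <- build_trajectories(list(mk(t95, "keep"), mk(t90, "drop")))
  expect_setequal(unique(trajs$cell_id), "keep")
  # constant trace + constant reporter collapses to a repeated point
  flat <- new_trace("flat", seq(0, 2, by = 5 / 60),
                    rep(1.1, 25), reporter = rep(3, 25))
  tf <- build_trajectories(list(flat))
  expect_true(all(tf$inv_mean == 3))
  expect_true(all(tf$erk_metric == 0))
  # missing reporter errors, naming the channel
  bare <- new_trace("bare", seq(0, 2, by = 5 / 60), rep(1, 25))
  expect_error(build_trajectories(list(bare)), "reporter")
})

test_that("segments are binned by start point and averaged per block", {
  # one segment pointing right: only its start block carries an arrow
  trajs <- make_trajs(rbind(c(0.1, 0.1), c(0.3, 0.1)))
  pd <- bin_and_average(trajs, n_blocks = c(2, 2), xlim = c(0, 1),
                        ylim = c(0, 1))
  expect_equal(nrow(pd$blocks), 1)
  expect_equal(pd$blocks$ix, 1)
  expect_equal(pd$blocks$iy, 1)
  expect_equal(pd$blocks$dx, 0.2)
  expect_equal(pd$blocks$dy, 0)

  # two equal-and-opposite segments in one block cancel
  trajs2 <- make_trajs(rbind(c(0.1, 0.1), c(0.3, 0.2)),
                       rbind(c(0.12, 0.12), c(-0.08, 0.02)))
  pd2 <- bin_and_average(trajs2, n_blocks = c(2, 2), xlim = c(0, 1),
                         ylim = c(0, 1))
  b11 <- pd2$blocks[pd2$blocks$ix == 1 & pd2$blocks$iy == 1, ]
  expect_equal(b11$dx, 0, tolerance = 1e-12)
  expect_equal(b11$dy, 0, tolerance = 1e-12)

  # known drift recovered within Monte Carlo error
  set.seed(5)
  drift <- lapply(1:500, function(i) {
    x0 <- stats::runif(1, 0.3, 0.4)
    y0 <- stats::runif(1, 0.3, 0.4)
    rbind(c(x0, y0), c(x0 + 0.05 + stats::rnorm(1, 0, 0.01),
                       y0 - 0.02 + stats::rnorm(1, 0, 0.01)))
  })
  pdd <- bin_and_average(do.call(make_trajs, drift), n_blocks = c(2, 2),
                         xlim = c(0, 1), ylim = c(0, 1))
  b <- pdd$blocks[which.max(pdd$blocks$n), ]
  expect_lt(abs(b$dx - 0.05), 0.005)
  expect_lt(abs(b$dy + 0.02), 0.005)

  # segment conservation
  expect_equal(pdd$n_segments, 500)
  expect_equal(sum(pdd$blocks$n), 500)
})

test_that("normalization reproduces the stated transition-probability formula", {
  # arrow (0.3, 0.1) with unit maxima: r_x = 0.75, r_y = 0.25
  trajs <- make_trajs(rbind(c(0, 0), c(0.3, 0.1)),
                      rbind(c(1, 1), c(1, 1)))     # pins maxima, zero arrow
  pd <- normalize_and_transition(bin_and_average(trajs, n_blocks = c(2, 2)))
  mov <- pd$blocks[pd$blocks$n == 1 & pd$blocks$ix == 1 & pd$blocks$iy == 1, ]
  expect_equal(mov$xp, 0.3)
  expect_equal(mov$yp, 0.1)
  expect_equal(mov$r_x, 0.75)
  expect_equal(mov$r_y, 0.25)
  # the zero-arrow block is flagged absent
  zero <- pd$blocks[pd$blocks$ix == 2 & pd$blocks$iy == 2, ]
  expect_true(is.na(zero$r_x) && is.na(zero$r_y))

  # axis-aligned arrow: r_x = 0, r_y = -1
  trajs2 <- make_trajs(rbind(c(0.5, 0.9), c(0.5, 0.5)))
  pd2 <- normalize_and_transition(bin_and_average(trajs2, n_blocks = c(2, 2)))
  expect_equal(pd2$blocks$r_x, 0)
  expect_equal(pd2$blocks$r_y, -1)

  # all-zero arrows are an error
  trajs3 <- make_trajs(rbind(c(0.4, 0.4), c(0.4, 0.4)))
  expect_error(normalize_and_transition(bin_and_average(
    trajs3, n_blocks = c(2, 2), xlim = c(0, 1), ylim = c(0, 1))), "zero")
})

test_that("|r_x| + |r_y| = 1 for every populated block of random diagrams", {
  for (s in 1:20) {
    trajs <- random_trajs(n_cells = 8, n_steps = 15, seed = 300 + s)
    pd <- normalize_and_transition(bin_and_average(trajs, n_blocks = c(5, 5)))
    tot <- abs(pd$blocks$r_x) + abs(pd$blocks$r_y)
    expect_true(all(is.na(tot) | abs(tot - 1) < 1e-12))
    expect_gt(sum(is.finite(tot)), 0)
    # segment conservation for every diagram
    n_pairs <- sum(table(trajs$cell_id) - 1)
    expect_equal(sum(pd$blocks$n), n_pairs)
  }
})

test_that("transition probabilities are invariant to reporter rescaling", {
  trajs <- random_trajs(n_cells = 6, n_steps = 12, seed = 77)
  pd1 <- normalize_and_transition(bin_and_average(trajs, n_blocks = c(4, 4)))
  trajs2 <- trajs
  trajs2$inv_mean <- trajs2$inv_mean * 1000
  pd2 <- normalize_and_transition(bin_and_average(trajs2, n_blocks = c(4, 4)))
  expect_equal(pd2$blocks$r_x, pd1$blocks$r_x, tolerance = 1e-12)
  expect_equal(pd2$blocks$r_y, pd1$blocks$r_y, tolerance = 1e-12)
})

test_that("degenerate plane extents are rejected", {
  trajs <- make_trajs(rbind(c(0, 0.2), c(0, 0.4)))   # zero x-range
  expect_error(bin_and_average(trajs, n_blocks = c(2, 2)), "degenerate")
})
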