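test_that("ring counts match brute-force pair enumeration", {
  # two points at distance 30: the covering ring counts the pair twice
  fld <- field_rect(100, 100)
  pts <- rbind(c(10, 50), c(40, 50))
  res <- rdf(pts, fld, r_max = 100, dr = 10, n_ref = 5, seed = 1)
  expect_equal(res$N[res$r_center == 35], 2)
  expect_equal(sum(res$N), 2)

  # random sets vs the double loop, every ring
  set.seed(42)
  for (rep in 1:5) {
    pts <- cbind(stats::runif(40, 0, 100), stats::runif(40, 0, 100))
    res <- rdf(pts, fld, r_max = 60, dr = 10, n_ref = 2, seed = 1)
    want <- vapply(res$r_center, function(rc)
      oracle_pair_count(pts, rc - 5, rc + 5), integer(1))
    expect_equal(res$N, as.numeric(want))
    ref <- pts[1:7, , drop = FALSE]
    tgt <- pts[8:40, , drop = FALSE]
    resx <- cross_rdf(ref, tgt, fld, r_max = 60, dr = 10, n_ref = 2, seed = 1)
    wantx <- vapply(resx$r_center, function(rc)
      oracle_cross_count(ref, tgt, rc - 5, rc + 5), integer(1))
    expect_equal(resx$N, as.numeric(wantx))
  }
})

test_that("the null envelope is deterministic and centred on unity", {
  fld <- field_rect(400, 400)
  env1 <- null_envelope(fld, 400, n_realizations = 20, seed = 5)
  env2 <- null_envelope(fld, 400, n_realizations = 20, seed = 5)
  expect_identical(env1$ci_low, env2$ci_low)
  expect_true(all(abs(env1$null_mean - 1) < 0.1))
  expect_true(all(env1$ci_low <= env1$null_mean &
                    env1$null_mean <= env1$ci_high))
  expect_error(null_envelope(fld, 400, n_realizations = 1), "realizations")
})

test_that("CSR patterns stay inside the envelope at most radii", {
  fld <- field_rect(400, 400)
  env <- null_envelope(fld, 500, n_realizations = 50, seed = 8)
  rc <- attr(env, "ref_counts")
  dev <- 0L
  tot <- 0L
  for (s in 1:15) {
    pat <- simulate_spatial_pattern(
      spatial_sim_config(seed = 800 + s, n_points = 500, field = c(400, 400)))
    cl <- classify_rdf(rdf(pat, fld, ref_counts = rc), env)
    dev <- dev + sum(cl != "consistent_with_null", na.rm = TRUE)
    tot <- tot + sum(!is.na(cl))
  }
  expect_lte(dev / tot, 0.10)
})

test_that("Thomas-clustered patterns exceed the envelope at small radii", {
  fld <- field_rect(400, 400)
  env <- null_envelope(fld, 700, n_realizations = 50, seed = 9)
  pat <- simulate_spatial_pattern(
    spatial_sim_config(seed = 4, n_points = 700, field = c(400, 400),
                       process = "thomas_cluster", cluster_sd = 25))
  res <- rdf(pat, fld, ref_counts = attr(env, "ref_counts"))
  cl <- classify_rdf(res, env)
  small <- res$r_center < 50
  expect_true(all(res$g[small] > 1))
  expect_true(any(cl[small] == "clustered"))
})

test_that("classification rules follow the stated envelope logic", {
  mk_rdf <- function(g) structure(
    data.frame(r_center = c(5, 15), N = 1, N_ref = 1, g = g),
    mode = "single", class = c("rdf_result", "data.frame"))
  env <- data.frame(r_center = c(5, 15), null_mean = 1,
                    ci_low = 0.8, ci_high = 1.2)
  expect_equal(classify_rdf(mk_rdf(c(1.5, 1.0)), env),
               c("clustered", "consistent_with_null"))
  expect_equal(classify_rdf(mk_rdf(c(0.7, 1.3)), env, mode = "cross"),
               c("segregated", "grouped"))
  expect_equal(classify_rdf(mk_rdf(c(0.7, NA)), env)[2], NA_character_)
  expect_error(classify_rdf(mk_rdf(c(1, 1)), env[1, ]), "grids")
})

test_that("a single reference point still yields a finite cross RDF", {
  fld <- field_rect(200, 200)
  ref <- matrix(c(100, 100), ncol = 2)
  set.seed(3)
  tgt <- cbind(stats::runif(200, 0, 200), stats::runif(200, 0, 200))
  res <- cross_rdf(ref, tgt, fld, r_max = 80, dr = 10, n_ref = 10, seed = 2)
  expect_true(all(is.finite(res$g)))
  expect_error(cross_rdf(ref[0, , drop = FALSE], tgt, fld), "non-empty")
})

test_that("the dilated field mask approximates simple geometries", {
  # points filling a square densely: field ~ the square
  grid <- as.matrix(expand.grid(seq(0, 200, by = 2), seq(0, 200, by = 2)))
  fld <- build_field_of_interest(grid, dilation_radius = 2, res = 1)
  expect_lt(abs(fld$area - 200^2) / 200^2, 0.05)
  # a tight cluster gives one disc-like blob
  clus <- rbind(c(50, 50), c(51, 50), c(50, 51), c(49, 50))
  fld2 <- build_field_of_interest(clus, dilation_radius = 10, res = 0.5)
  expect_lt(abs(fld2$area - pi * 100) / (pi * 100), 0.25)
  # dilation radius -> 0 shrinks the area toward 0
  fld3 <- build_field_of_interest(clus, dilation_radius = 0.25, res = 0.1)
  expect_lt(fld3$area, 2)
  expect_error(build_field_of_interest(clus[1:2, ], 5), "3 points")
  # sampling stays inside the mask
  fld4 <- build_field_of_interest(clus, dilation_radius = 10, res = 0.5)
  set.seed(1)
  smp <- erkdyn:::sample_in_field(fld4, 500)
  expect_true(all(sqrt((smp[, 1] - 50)^2 + (smp[, 2] - 50)^2) < 13))
})
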