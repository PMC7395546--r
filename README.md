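# erkdyn — pulsatile ERK dynamics in single epidermal cells

ERK MAPK activity in epidermal keratinocytes is not a single number per
cell: on top of a slowly varying *basal* level, cells fire short (~0.25 h)
stochastic *pulses* of activity, and the balance between basal level and
pulsing tracks cell fate — highly pulsing basal cells proliferate, pulse
shutdown accompanies the onset of terminal differentiation, and low-pulsing
cells cluster spatially on the scale of epidermal proliferative units
(~25–50 µm). `erkdyn` implements the quantitative machinery needed to make
those statements from tracked single-cell FRET/CFP biosensor time series
and marked cell-position maps, together with a synthetic-data generator so
that every stage can be exercised and tested without imaging data.

Intended users: quantitative cell biologists and image-analysis people who
already have per-cell tracker exports (cell id, frame, time, position, CFP
and FRET intensities, optionally a differentiation-reporter intensity) and
want the downstream statistics.

## What it computes

- **Pulse detection** (`detect_pulses`). Pulses are strict local maxima of
  the (smoothed) ratio R(t) = FRET/CFP with topographic prominence ≥ a
  threshold and a minimum peak separation. Amplitude = prominence,
  duration = full width at half prominence, frequency = peak count /
  observed span. Pulse timing is stochastic: interpulse intervals Δt
  follow an exponential law, which `fit_exponential` checks by ML fit
  (rate = 1/mean) plus a Kolmogorov–Smirnov test. Because pulses closer
  than about one pulse duration merge at 5-min sampling, the detected
  frequency saturates with the true rate; `calibrate_detection` +
  `estimate_rate_from_frequency` invert the simulated detector response to
  recover the underlying rate.
- **Variance pulse-level metrics** (`moving_variance`,
  `instantaneous_variance`, `pulse_level_score`). The sample variance of
  R(t) in overlapping 50-min windows is a continuous per-cell pulse-level
  readout (zero iff the windowed signal is constant); the variance across
  cells at a fixed time point is its population-level counterpart.
- **Phase diagrams** (`build_trajectories`, `bin_and_average`,
  `normalize_and_transition`). Each cell traces a path in the plane of
  (reporter moving mean, ERK moving variance). Path displacements are
  binned into a regular grid; per-block mean arrows are rescaled by the
  axis maxima, x′ = x/max(Inv), y′ = y/max(Var), and converted to signed
  transition probabilities r_x = x′/(|x′|+|y′|), r_y = y′/(|x′|+|y′|),
  so that |r_x| + |r_y| = 1 in every populated block.
- **Spatial clustering** (`rdf`, `cross_rdf`, `null_envelope`,
  `classify_rdf`, `build_field_of_interest`). The radial distribution
  function g(r) = N(r,Δr)/N_ref(r,Δr) compares observed ring counts with
  counts for randomly placed points in the same field of interest; a
  50-realization Monte Carlo envelope under complete spatial randomness
  classifies each radius as clustered/dispersed (one population) or
  grouped/segregated (rings around one pulse class, counting the other).
- **Synthetic data** (`sim_config`, `simulate_trace`, `simulate_cohort`,
  `spatial_sim_config`, `simulate_spatial_pattern`). Raised-cosine pulses
  with exponential interpulse intervals (default mean 1.52 h, duration
  0.25 h) on a basal ratio ~1.1, 5-min sampling for 24 h, Gaussian noise
  far below pulse amplitude, optional pulse shutdown coupled to a rising
  reporter; point patterns with CSR or Thomas-cluster geometry and
  independent or cluster-linked pulse-class marks.

## Worked example

```r
library(erkdyn)

cfg <- sim_config(seed = 8, pulse_rate = 1 / 1.52)   # mean interval 1.52 h
trace <- simulate_trace(cfg, cell_id = "cell_8")
trace
#> <erk_trace 'cell_8': 289 samples, 0.00-24.00 h, ratio 1.048-1.401>

pulses <- detect_pulses(trace, min_prominence = 0.05)
pulses
#> <pulse_set 'cell_8': 12 pulses in 24.00 h (0.50 /h)>
round(interpulse_intervals(pulses), 2)
#>  [1] 0.50 1.50 1.92 0.75 1.17 2.33 1.25 2.58 2.83 4.33 1.00

pulse_level_score(moving_variance(trace, window = 50))
#> [1] 0.00223

pat <- simulate_spatial_pattern(
  spatial_sim_config(seed = 5, n_points = 1400, field = c(400, 400),
                     mark_model = "clustered_low_pulse"))
fld <- field_rect(400, 400)
hi <- pat[pat$mark == "high", ]; lo <- pat[pat$mark == "low", ]
env <- null_envelope(fld, nrow(lo), n_realizations = 50, seed = 1,
                     ref_points = hi)
res <- cross_rdf(hi, lo, fld, ref_counts = attr(env, "ref_counts"))
data.frame(r = res$r_center, g = round(res$g, 2),
           class = classify_rdf(res, env))[1:5, ]
#>    r    g      class
#> 1  5 0.52 segregated
#> 2 15 0.55 segregated
#> 3 25 0.59 segregated
#> 4 35 0.65 segregated
#> 5 45 0.68 segregated
```

The 12 detected pulses in 24 h (0.50 /h) with exponential-looking
intervals are the single-cell pulse statistics; the pulse-level score
0.00223 ratio² summarises the cell's pulsing via the 50-min moving
variance; and the cross-RDF values well below 1 at r < 50 µm, classified
`segregated` against the CSR envelope, show that low-pulsing cells avoid
the neighbourhoods of high-pulsing cells — the spatial signature of
clustered low-pulse domains.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic
cohorts and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R     # cohorts + point patterns
Rscript analysis/02_pulse_statistics.R     # detection, intervals, states
Rscript analysis/03_variance_metrics.R     # moving/instantaneous variance
Rscript analysis/04_phase_diagram.R        # transition-probability field
Rscript analysis/05_spatial_clustering.R   # RDF clustering/segregation
```

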