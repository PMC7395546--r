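---
title: "Methods: quantifying pulsatile ERK dynamics and their spatial organisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pulsatile ERK dynamics and their spatial organisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erkdyn)
```

`erkdyn` analyses single-cell ERK activity recorded as a FRET/CFP
biosensor ratio. This vignette is the package's methods account: the
models and estimators, the parameters that matter and why their defaults
are what they are, the numerical conventions, and what the synthetic
benchmarks do and do not demonstrate.

## The signal model

Per cell we observe a dimensionless ratio trace $R(t)$ on a uniform grid
(5-min sampling is typical; minutes-scale intervals in general). The
working decomposition is

$$R(t) = B(t) + \sum_i A\,\phi\!\left(\frac{t - t_i}{D}\right) + \varepsilon(t),$$

a slowly varying basal level $B$, pulses of amplitude $A$ and duration $D$
at stochastic times $t_i$, and measurement noise $\varepsilon$ of standard
deviation well below $A$. Two assumptions drive everything downstream:

* **Pulse timing is Poissonian.** Interpulse intervals are exponential
  with mean $1/\lambda$; pulses are stochastic events, not oscillations.
  This motivates the exponential ML fit with a KS check
  (`fit_exponential`) and the Poisson pulse trains in the generator.
* **Noise is much smaller than pulses.** This is what lets windowed
  variance serve as a pulse-level readout and prominence thresholds
  separate pulses from noise.

The synthetic generator (`sim_config`, `simulate_trace`) realises exactly
this model with a raised-cosine pulse shape
$\phi(u) = \tfrac12(1 + \cos 2\pi u)$ on $|u| < 1/2$: smooth, compactly
supported, and agnostic about the unknown true waveform beyond its ~0.25 h
duration. Overlapping pulses add. Defaults are the study conditions the
package emulates: 5-min sampling for 24 h, mean interpulse interval
1.52 h, pulse duration 0.25 h, basal ratio 1.1 (within the 1.0–1.2 band
typical of the sensor), amplitude 0.15 and noise SD 0.02 ratio units. The
amplitude is not pinned down by published summary statistics beyond being
much larger than noise; 0.15 with noise 0.02 (SNR 7.5) is our one-time
choice of a realistic regime. With
`reporter_onset_model = "coupled_to_pulse_shutdown"` the pulse train stops
at a per-cell shutdown time and a differentiation-reporter signal rises as
a saturating exponential (plateau 100 a.u., time constant 4 h): the
reporter waveform is phenomenological — only the coincidence of pulse
shutdown and reporter onset is the modelled biology.

Cohorts derive per-trace sub-seeds from one master seed by multiplicative
hashing, so cohorts are reproducible while traces are uncorrelated.

## Pulse detection

`detect_pulses` finds strict local maxima of the smoothed ratio, filters
them by topographic prominence, enforces a minimum peak separation
(greedy, in time order), and reports amplitude (prominence), duration
(full width at half prominence, by linear interpolation) and frequency
(count over observed span — observed, not nominal, because tracked cells
have unequal lifetimes).

Parameter defaults, all in minutes where applicable:

* `smoothing_window = 15`: a centered moving *average*. A moving median of
  this width would annihilate a 0.25-h pulse at 5-min sampling (the pulse
  occupies three samples, `[0.25A, A, 0.25A]`, and the window median is
  the flank value), whereas the average halves it but preserves a clean
  maximum — effectively a matched filter for the pulse width. Edge windows
  shrink rather than produce NAs.
* `min_prominence = NULL`: per-trace default $3\hat\sigma$ with
  $\hat\sigma = \mathrm{mad}(\Delta R)/\sqrt2$, a robust first-difference
  noise estimate, floored at $10^{-8}$ so that rounding wiggle on
  noise-free traces never counts as peaks. The default favours
  specificity: pulse-free control traces should yield a near-zero
  frequency. It is deliberately overridden in dense-pulse benchmarks
  (we use amplitude/3 there), because pulse slopes inflate the
  first-difference spread once pulses occupy a large fraction of samples.
* `min_separation = 15`: below the typical pulse duration, so a noisy
  plateau is not double-counted.
* Non-uniform sampling (e.g. mixed 5- and 15-min acquisition) is linearly
  interpolated onto the median interval first, with a warning, so both
  acquisition modes share one code path.

Ties in the class gates resolve upward: `classify_pulse_class` calls a
frequency exactly at 1.5 pulses/h `"high"`, and `gate_basal` calls a mean
ratio exactly at 1.2 `"high"` — deterministic and documented, since only
strict wording exists for the thresholds themselves.

### Detectability and rate recovery

At 5-min sampling, two pulses closer than roughly half a pulse duration
produce a single maximum, and somewhat larger gaps leave a saddle too
shallow to pass the prominence filter; the separation filter adds an
explicit dead time. Detected frequency therefore saturates as the true
rate grows — this is a resolution limit of the data, not an
implementation defect, and no counting detector at this sampling evades
it. Two estimators address it:

* `estimate_pulse_rate`: the classical non-paralyzable dead-time
  correction $\hat\lambda = 1/(\overline{\Delta t} - \tau)$ from detected
  intervals. Adequate when pulses are mostly well separated
  ($\lambda \tau \ll 1$); increasingly biased beyond that, because the
  effective dead time is rate-dependent.
* `calibrate_detection` + `estimate_rate_from_frequency`: the unfolding
  route. The detector response $f(\lambda)$ (detected frequency vs true
  rate) is tabulated by forward simulation under the assumed pulse shape,
  amplitude and noise, made monotone by isotonic regression, and inverted
  by interpolation. This is the estimator the package's recovery
  benchmarks use across 0.5–3 pulses/h. Its validity rests on the assumed
  waveform and noise level; with experimental data those would first be
  estimated from well-isolated pulses.

A related finite-window effect: complete interpulse intervals observed in
a window of length $T$ are length-biased short by roughly a factor
$(1 - 1/\lambda T)$, about 6% for a 1.5-h mean in 24 h. Interval means
should therefore be compared on long recordings (our benchmark uses 96-h
traces, where the bias is ~1.5%), while KS goodness-of-fit at per-cohort
sample sizes is insensitive to it.

## Variance as a pulse-level measure

Peak counting is discrete; the variance of the ratio is a continuous
pulse-level readout that captures amplitude and number of pulses at once.
Two flavours:

* `moving_variance`: per cell, the sample variance in overlapping
  centered windows of 50 min, stepped by one sampling interval. 50 min is
  short enough that the basal level is effectively constant within a
  window, long enough to contain a whole 0.25-h pulse. Windows are
  defined on time, not frame count, so different sampling intervals share
  one definition; partial windows at the edges are dropped and windows
  with fewer than three in-window samples (gaps) are skipped. The time
  average of the window variance is the per-cell pulse-level score
  (`pulse_level_score`).
* `instantaneous_variance`: across cells, the sample variance of the
  ratio at each timepoint observed in at least two cells.

Both use the $n-1$ denominator; the choice is a convention fixed here
(and recorded in this vignette) so every downstream number is
well-defined. Variance is zero exactly when the windowed signal is
constant, and both implementations are tested against naive per-window
recomputation at $10^{-12}$ relative tolerance.

## Phase diagrams and transition probabilities

For cells carrying a differentiation reporter, `build_trajectories` pairs
the 50-min moving mean of the reporter (x) with the 50-min moving
variance — or moving mean — of ERK (y), per window position, giving each
cell a trajectory in that plane. Only traces spanning strictly more than
90 min enter (strict, following the "more than 90 min" convention; at
least two full windows are needed for a displacement anyway).

`bin_and_average` divides the plane into a regular grid (default 10×10
spanning $[0, \max]$ on each axis; granularity comparable to the
published diagrams) and assigns every consecutive-point displacement to
the block containing its *start* point — the forward-difference reading
of "trajectories that lay within each block". Blocks are half-open with
the upper edge belonging to the higher block, except the global maximum,
which closes the top block. The per-block mean displacement is the arrow.

`normalize_and_transition` rescales arrow components by the *global* data
maxima (not per cell — the maxima are properties of the whole diagram),
$x' = x/\max(\text{reporter mean})$, $y' = y/\max(\text{ERK metric})$,
then forms signed transition probabilities
$r_x = x'/(|x'|+|y'|)$, $r_y = y'/(|x'|+|y'|)$, so $|r_x|+|r_y|=1$
identically for every nonzero arrow; zero arrows get `NA` probabilities
rather than an arbitrary direction. The identity, segment conservation,
and invariance of $(r_x, r_y)$ under rescaling of reporter units are all
tested exhaustively on random diagrams. Blocks visited by few segments
are reported with their segment count `n` so users can mask them when
plotting; no minimum count is imposed in the computation.

## Spatial statistics: RDF against a Monte Carlo CSR null

For marked cell maps, the radial distribution function is the ratio
$g(r) = N(r, \Delta r)/N_\mathrm{ref}(r, \Delta r)$, where $N$ sums, over
every cell of interest, the cells found in the half-open annulus
$[r - \Delta r/2, r + \Delta r/2)$ around it, and $N_\mathrm{ref}$ is the
same count for randomly placed points in the field of interest at matched
intensity. Defaults $\Delta r = 10$ µm (about one cell diameter) on a
5–145 µm grid resolve the tens-of-µm cluster scales of interest. Edge
effects cancel in the ratio because both numerator and denominator live
in the same field — the field mask (`build_field_of_interest`, union of
discs around observed cells, rasterized at 2 µm) *is* the edge
correction; no analytic correction is applied.

Numerical conventions:

* $N_\mathrm{ref}$ is averaged over 20 random realizations (configurable)
  — a single realization would add substantial Monte Carlo noise to every
  $g$ value. The envelope and any observed curve compared against it share
  one $N_\mathrm{ref}$ estimate (the envelope object carries it), so the
  comparison is self-consistent.
* The 95% envelope is the 2.5/97.5 percentile of 50 null realizations,
  computed with `quantile(type = 6)`. The choice of plotting position
  matters: with the default type 7 at $n = 50$, a *new* null realization
  falls outside the envelope roughly 9% of the time, because the
  interpolated bounds sit near the 2nd/49th order statistics; type 6
  ($(n+1)p$ positions) gives expected coverage matching the nominal
  level, which is the property a simulation envelope is used for.
* Radii where $N_\mathrm{ref} = 0$ are reported `NA`, never divided.
* Cross mode (`cross_rdf`) builds rings around one group (e.g.
  high-pulsing) and counts the other; its null randomizes the target
  positions at matched intensity with the reference cells fixed. Below
  the envelope means the groups are segregated; above, grouped.
* Classification is per radius: clustered/dispersed (single population)
  or grouped/segregated (cross), else consistent with the null. With ~15
  radii per curve, isolated single-radius exceedances at the nominal
  ~5% rate are expected even for random patterns; conclusions should rest
  on runs of radii at the biologically relevant scale, which is how the
  package's own benchmarks phrase their checks.

## The synthetic benchmarks: what they show and what they do not

The generator reproduces the statistical structure the estimators assume:
Poisson pulse trains, a single stereotyped pulse shape, stationary
Gaussian noise, a clean step from pulsing to reporter rise, uniform or
Thomas-clustered geometry with marks either independent or tied to
cluster membership (a pseudo pulse frequency depressed near cluster
parents; the lowest half are the "low" class, mimicking least/most
pulsatile selections of equal size). Passing tests on these cohorts
demonstrates correctness of the estimators under the model and their
calibration at realistic sizes (e.g. 80–120 cells per cohort, 24-h
traces, 1400-cell maps in 400×400 µm, 50-realization envelopes — the
problem sizes used throughout the test suite and analysis scripts).

They do not demonstrate robustness to what real data add: basal drift
and photobleaching, amplitude heterogeneity between cells, tracking
errors and gaps, reporter bleed-through, non-stationary cell density, or
pulse waveforms that differ from the raised cosine. The detector-response
calibration in particular inherits the assumed waveform and noise level;
on experimental data it must be re-derived from measured pulse
parameters, and the variance metrics should be read jointly with basal
trends rather than as pure pulse measures when $B(t)$ drifts within a
window.

## Degenerate inputs and error policy

Constructors validate their invariants (positive sampling interval and
duration, non-negative rate and noise, pulse duration below the mean
interval, positive field area, in-range shutdown times). Traces need two
samples; detection needs three; exponential fits need ten intervals;
RDFs need two points; fields need three; moving variance needs one full
window — each violation is a clear error, not a silent NA. Empty results
that are legitimate (no traces pass the duration filter, no shared
timepoints, a pattern of one point) return empty containers, with a
warning where the emptiness is likely surprising.
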