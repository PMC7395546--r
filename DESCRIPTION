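Package: erkdyn
Title: Pulsatile ERK Dynamics: Pulse Detection, Variance Metrics and
    Spatial Clustering for Single-Cell FRET Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for pulsatile ERK MAPK activity in single
    epidermal cells measured with a FRET/CFP ratio biosensor. Simulates
    stochastic pulse trains with exponential interpulse intervals and marked
    two-dimensional point patterns; ingests tracked single-cell tables and
    computes the FRET/CFP ratio; detects activity pulses as local peaks and
    fits exponential interval distributions; quantifies pulse levels by
    instantaneous (cross-population) and moving-window variance; builds phase
    diagrams of ERK variability against a differentiation reporter with
    normalised transition probabilities; and tests spatial clustering or
    segregation of pulse classes with a radial distribution function against
    a Monte Carlo complete-spatial-randomness null.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
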