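# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so simulation functions do not perturb the
# global random sequence.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for trace/realization `index` under `master`.
# Multiplicative mixing in double precision; all intermediates < 2^53 so the
# arithmetic is exact, and the result fits in a 32-bit integer.
derive_subseed <- function(master, index) {
  s <- abs(as.numeric(master)) %% 2147483647
  v <- (s * 48271 + as.numeric(index) * 2654435) %% 2147483647
  as.integer(v + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
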