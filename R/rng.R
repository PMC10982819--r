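# Hierarchical seed derivation. A single cohort seed spawns per-patient and
# per-node substreams, so that generating patient i (node j) never depends on
# how many draws earlier patients consumed: cohorts are reproducible and
# order-independent. Arithmetic stays below 2^53 so the modular products are
# exact in doubles.
.mixSeed <- function(...) {
  x <- 104729
  for (v in c(...)) {
    x <- (x * 69069 + as.numeric(v) + 1) %% 2147483647
    x <- (x * 69069 + 12345) %% 2147483647
  }
  as.integer(x)
}

# Evaluate code under a given seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
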