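# Deterministic per-individual seed derivation.
#
# Every stochastic draw in a run flows from the scenario's root seed. Each
# individual (and each stage within an individual) gets its own derived seed,
# so changing n_individuals never perturbs the draws of earlier individuals.
# Mixing uses Lehmer multiplicative-congruential steps modulo the Mersenne
# prime 2^31 - 1; all intermediates stay below 2^47, exact in doubles.

MOD31 <- 2147483647

lehmer_step <- function(x) (x * 48271) %% MOD31

derive_seed <- function(root, index = 0L, stage = 0L) {
  x <- (abs(as.numeric(root)) %% MOD31) + 1
  x <- lehmer_step(x)
  x <- lehmer_step((x + as.numeric(index)) %% MOD31 + 1)
  x <- lehmer_step((x + as.numeric(stage)) %% MOD31 + 1)
  as.integer(x)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stage codes for substream derivation (stable across versions).
STAGE <- list(
  bank = 0L, person = 1L, events = 2L, schedule = 3L, sampling = 4L
)
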