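# Internal RNG helpers. All user-facing randomness goes through withSeed()
# so package functions never disturb the caller's RNG stream, and derived
# per-item seeds follow one documented mixing rule.

withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive the i-th sub-seed from a master seed: one multiplicative
# congruential step (multiplier 48271, modulus 2^31 - 1) offset by the
# ordinal. Deterministic, collision-free for corpus-sized i, and keeps
# every derived seed a valid 32-bit R integer.
mixSeed <- function(masterSeed, i) {
  m <- 2147483647
  as.integer(((as.numeric(masterSeed) %% m) * 48271 + as.numeric(i)) %% m)
}
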