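# Seed scoping helpers. Every stochastic operation takes an explicit seed
# and leaves the caller's RNG state untouched.

# Evaluate `code` under set.seed(seed), restoring the previous RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Deterministically derive a sub-seed < 2^31 from a master seed and an index.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 32771 + as.numeric(k) * 7919) %%
    2147483629L
}
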