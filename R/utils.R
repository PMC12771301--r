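# Run code with a local RNG state seeded from `seed`, restoring the global
# state afterwards. All package randomness flows through this (Mersenne
# Twister, R's default), so equal seeds give equal output on any platform.
with_local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-subject seed: a fixed affine hash of the cohort seed,
# group index (1 or 2) and subject index, reduced modulo a prime below
# 2^31 so it is always a valid R seed. Documented so cohorts are exactly
# reproducible subject by subject.
subject_seed <- function(seed, group_index, subject_index) {
  as.integer((as.numeric(seed) * 1000003 + group_index * 10007 +
                subject_index * 101) %% 2147483629)
}
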