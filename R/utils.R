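# Internal helpers: seeded evaluation that does not clobber the caller's RNG
# stream, and per-item seed derivation from a master seed.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seeds: Lehmer step keeps values in [1, 2^31 - 2] so they
# are always valid 32-bit set.seed() inputs whatever the master seed.
derive_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 2147483646 * 48271 + i * 10007) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values (NaN/Inf/NA)")
  invisible(x)
}
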