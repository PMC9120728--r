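# Seed-scoped randomness: every stochastic operation takes an explicit
# seed and leaves the caller's RNG state untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Stage seeds are derived from a master seed by fixed offsets so one
# master seed pins the whole pipeline (kept below 2^31 - 1).
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1000 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
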