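# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's
#' RNG state, so every generator in the package is a pure function of its
#' seed argument and never perturbs the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic child seeds derived from a master seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483647
}
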