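#' @importFrom rlang %||%
#' @importFrom generics tidy glance
#' @importFrom dplyr .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's RNG stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: every random stage of a pipeline draws
# its seed as derive_seed(master, counter) with a documented counter, so one
# master seed reproduces the whole artifact. Kept below 2^31 - 1.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 7919 + as.double(counter) * 104729 + 1) %%
               2147483647)
}

# round-half-up at `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}
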