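#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded operations never perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive per-unit child seeds from a master seed, kept within 32-bit range.
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}
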