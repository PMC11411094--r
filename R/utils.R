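#' Evaluate an expression with a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded generators do not disturb the session
#' stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# shared argument checks -----------------------------------------------------

stop_invalid <- function(invariant, detail) {
  stop(sprintf("invalid specification: %s (%s)", invariant, detail),
       call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_num <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
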