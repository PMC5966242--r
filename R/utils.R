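# Internal helpers.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
# seed = NA leaves the current stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

# Derive a sub-seed from a master seed; keeps results < 2^31.
.subSeed <- function(seed, k) {
  if (is.null(seed) || is.na(seed)) return(NA_integer_)
  (as.numeric(seed) * 1009 + 97 * k) %% 2147483629
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
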