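#' @keywords internal
#' @useDynLib apneafusion, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run code with a temporarily-seeded RNG, restoring global RNG state afterwards.
# All seeded operations in the package funnel through this so that a caller's
# RNG stream is never perturbed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 101 + offset) %% 2147483647)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
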