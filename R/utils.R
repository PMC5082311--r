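#' @keywords internal
"_PACKAGE"

## Evaluate expr under a temporary RNG seed; the global stream is untouched.
## seed = NULL means "use the current stream" (caller manages reproducibility).
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_number <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}
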