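#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# non-syntactic bindings used inside ggplot2::aes()
utils::globalVariables(c("epoch", "value", "split", "pair_mean", "pair_diff"))

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# validation failure distinct from runtime failure: the CLI maps it to exit 2
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("mm_validation_error", "error")))
}

assert_number <- function(x, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("'%s' must be a single finite number", field))
  }
  if (x < lo || x > hi) {
    stop_validation(sprintf("'%s' must be in [%s, %s], got %s", field, lo, hi, x))
  }
  as.numeric(x)
}

# All randomness in the package flows through explicit seeds; the global RNG
# state of the caller is never consumed or disturbed.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
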