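#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate `code` under a temporary RNG seed; NULL seed leaves the stream alone.
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

assert_finite_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}

assert_numeric_signal <- function(x, name = "signal", require_finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a non-empty numeric vector", name))
  }
  if (require_finite && !all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite samples", name))
  }
  invisible(x)
}

# Linear ramp over n samples ending exactly at `to` (the fixation that follows
# continues at `to`, so the start value is owned by the previous segment).
ramp_to <- function(from, to, n) {
  from + (to - from) * seq_len(n) / n
}
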