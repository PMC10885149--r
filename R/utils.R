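#' @keywords internal
"_PACKAGE"

# Trapezoidal integral of y over x (x ascending).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1L]) / 2)
}

# Simple condition-tagged logger: messages are emitted with a reason code so
# callers (and the pipeline manifest) can count dropped pixels/ROIs/rows.
pm_log <- function(code, fmt, ...) {
  message(sprintf("[%s] %s", code, sprintf(fmt, ...)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child RNG seed from a master seed and a stream index, kept well
# inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000 + stream) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
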