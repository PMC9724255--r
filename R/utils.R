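. <- NULL # soothe R CMD check for data.table NSE if ever used

# Internal argument checks -----------------------------------------------

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config("`%s` must be a single non-missing number", name)
  }
  if (x < lower || x > upper) {
    stop_config("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

check_fraction <- function(x, name) check_number(x, name, 0, 1)

# Clamp a numeric vector, recording whether clamping occurred.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a reproducible child seed from a base seed and an offset, kept
# inside the 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
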