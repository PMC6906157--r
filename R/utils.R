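# Internal helpers: seed derivation and small numerics.

# Derive a child seed from a parent seed and a stream index. Keeps results
# inside the positive 32-bit integer range so set.seed() never overflows.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  as.integer((abs(seed) * 48271 + index * 16807 + 12345) %% 2147483629L)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Population (divide-by-n) standard deviation along columns of a matrix.
pop_sd_cols <- function(x) {
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name, open_low = TRUE, open_high = TRUE) {
  lo_ok <- if (open_low) x > 0 else x >= 0
  hi_ok <- if (open_high) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop(sprintf("`%s` must be a probability in %s0, 1%s, got %s",
                 name, if (open_low) "(" else "[",
                 if (open_high) ")" else "]", format(x)), call. = FALSE)
  }
  invisible(x)
}
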