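# Internal helpers: seed derivation and validation.

# Deterministically combine a base seed with stream ids into a sub-seed in
# [1, 2^31 - 2]. Counter-based: every patient / epoch / noise draw gets its
# own stream derived from one user-facing integer seed.
derive_seed <- function(seed, ...) {
  ids <- c(as.double(seed), as.double(unlist(list(...))))
  h <- 0
  for (x in ids) {
    # multiplier < 2^17 keeps h * m + x exactly representable in doubles
    h <- (h * 69069 + x + 0x9E37) %% 2147483647
  }
  as.integer(h %% 2147483645L + 1L)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s, got %s.", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s, got %s.", name, lower, x))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s, got %s.", name, upper, x))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d, got %s.",
                  name, min, paste(x, collapse = ", ")))
  }
  as.integer(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
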