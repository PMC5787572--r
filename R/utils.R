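# Internal helpers shared across modules.

# Deterministic per-stage seed derivation from one root seed.  Kept inside
# 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973 + 17) %% 2147483647)
}

stop_if_not_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

stop_if_negative <- function(x, name = deparse(substitute(x))) {
  if (any(x < 0)) {
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

# Euclidean column norms.
col_norms <- function(x) sqrt(colSums(x^2))

# t-based confidence bounds over replicate means.  With a single replicate
# or zero spread the bound collapses to the mean.
ci_bounds <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(lower = m, upper = m))
  se <- sd(x) / sqrt(n)
  tcrit <- qt(1 - (1 - level) / 2, df = n - 1L)
  c(lower = m - tcrit * se, upper = m + tcrit * se)
}
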