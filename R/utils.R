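# Internal helpers shared across the package.

# Deterministic sub-seed derivation so that every stochastic component
# (permutations, replicates, selection screens) is reproducible in isolation
# from (master seed, purpose tag, index).  Mixes through a Lehmer-style
# recurrence mod 2^31 - 1; all intermediates stay below 2^53 so double
# arithmetic is exact.
derive_seed <- function(seed, purpose, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- abs(as.double(seed)) %% 2147483647
  for (ch in utf8ToInt(as.character(purpose))) {
    h <- (h * 69069 + ch) %% 2147483647
  }
  h <- (h * 69069 + as.double(index) %% 2147483647) %% 2147483647
  as.integer(h)
}

# Lexicographic (a < b) pair grid over m SNPs: a 2-column integer matrix with
# choose(m, 2) rows, ordered a-major.
pair_grid <- function(m) {
  stopifnot(m >= 2)
  a <- rep.int(seq_len(m - 1L), (m - 1L):1L)
  b <- sequence((m - 1L):1L, from = 2L:m)
  cbind(a = a, b = b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
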