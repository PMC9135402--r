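# Add-only arbitrary-precision non-negative integers.
#
# Path counts on genotype networks grow combinatorially, so the dynamic
# programme needs exact integer addition beyond 2^53. A count is stored as a
# little-endian numeric vector of base-1e15 chunks: adding two chunks stays
# below 2^53, so plain double arithmetic per chunk is exact.

.BIG_BASE <- 1e15

big_from_num <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x))
  if (x == 0) return(0)
  out <- numeric(0)
  while (x > 0) {
    out <- c(out, x %% .BIG_BASE)
    x <- floor(x / .BIG_BASE)
  }
  out
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- if (s[i] >= .BIG_BASE) 1 else 0
    if (carry) s[i] <- s[i] - .BIG_BASE
  }
  if (carry) s <- c(s, 1)
  s
}

big_is_zero <- function(a) all(a == 0)

# Lossy: Inf when the exact value exceeds double range.
big_to_num <- function(a) {
  sum(a * .BIG_BASE^(seq_along(a) - 1))
}

big_to_string <- function(a) {
  if (big_is_zero(a)) return("0")
  hi <- length(a)
  parts <- vapply(rev(seq_len(hi)), function(i) {
    if (i == hi) sprintf("%.0f", a[i]) else sprintf("%015.0f", a[i])
  }, character(1))
  paste(parts, collapse = "")
}
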