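# Naive reference implementation, deliberately independent of the package's
# vectorised path: materialises every subsequence, symbolises its
# differences case by case, and counts the strings in a named list.
naive_symbol <- function(d, delta, gamma) {
  if (d > gamma) return(2L)
  if (d > delta) return(1L)          # delta < d <= gamma
  if (d >= -delta) return(0L)        # |d| <= delta
  if (d >= -gamma) return(-1L)       # -gamma <= d < -delta
  -2L
}

naive_histogram <- function(x, m, delta, gamma) {
  counts <- list()
  for (i in seq_len(length(x) - m + 1)) {
    sub <- x[i:(i + m - 1)]
    syms <- integer(m - 1)
    for (j in seq_len(m - 1)) {
      syms[j] <- naive_symbol(sub[j] - sub[j + 1], delta, gamma)
    }
    key <- paste(syms, collapse = ",")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  unlist(counts)
}

naive_slpen <- function(x, m, delta, gamma) {
  counts <- naive_histogram(x, m, delta, gamma)
  p <- counts / length(counts)
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force integer maximiser of the uniform-histogram SlpEn expression.
brute_force_kmax <- function(n) {
  k <- 2:(n - 1)
  f <- (n / k) * log2(k^2 / n)
  k[which.max(f)]
}
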