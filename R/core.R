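#' Slope-entropy parameter set
#'
#' Bundles and validates the three tunable parameters of Slope Entropy:
#' the embedding dimension `m` (length of each overlapping subsequence;
#' symbol strings have length `m - 1`), the flat-band threshold `delta`
#' and the steep-band threshold `gamma`. Differences between consecutive
#' samples are mapped to the five-symbol alphabet \{+2, +1, 0, -1, -2\}
#' according to where they fall relative to `delta` and `gamma`.
#'
#' Defaults (`m = 6`, `delta = 0.001`, `gamma = 0.8`) are the standard
#' operating point for physiological signal analysis with this measure.
#'
#' @param m Integer embedding dimension, at least 3.
#' @param delta Flat-band threshold; differences with `|d| <= delta` map to 0.
#'   Must satisfy `0 <= delta < gamma`.
#' @param gamma Steep-band threshold; differences with `d > gamma` map to +2.
#' @return A list of class `slpen_params` with elements `m`, `delta`, `gamma`.
#' @examples
#' slpen_params()
#' slpen_params(m = 4, gamma = 0.2)
#' @export
slpen_params <- function(m = 6, delta = 0.001, gamma = 0.8) {
  if (length(m) != 1L || !is.numeric(m) || !is.finite(m) || m != round(m) || m < 3)
    abort("`m` must be a single integer >= 3.", class = "slpen_invalid_input")
  if (length(delta) != 1L || !is.numeric(delta) || !is.finite(delta))
    abort("`delta` must be a single finite number.", class = "slpen_invalid_input")
  if (length(gamma) != 1L || !is.numeric(gamma) || !is.finite(gamma))
    abort("`gamma` must be a single finite number.", class = "slpen_invalid_input")
  if (delta < 0 || delta >= gamma)
    abort("Thresholds must satisfy 0 <= delta < gamma.", class = "slpen_invalid_input")
  structure(list(m = as.integer(m), delta = delta, gamma = gamma),
            class = "slpen_params")
}

#' @export
print.slpen_params <- function(x, ...) {
  cat(sprintf("<slpen_params> m = %d, delta = %g, gamma = %g\n",
              x$m, x$delta, x$gamma))
  invisible(x)
}

check_series <- function(x, m = NULL) {
  if (!is.numeric(x))
    abort("The time series must be numeric.", class = "slpen_invalid_input")
  if (length(x) < 2L)
    abort("The time series must contain at least 2 samples.",
          class = "slpen_invalid_input")
  if (!all(is.finite(x)))
    abort("The time series contains non-finite samples.",
          class = "slpen_invalid_input")
  if (!is.null(m) && length(x) < m)
    abort(sprintf("Series too short: N = %d < m = %d.", length(x), m),
          class = "slpen_series_too_short")
  invisible(x)
}

#' Map slope differences to the five-symbol alphabet
#'
#' Applies the threshold partition of the real line: `+2` if `d > gamma`,
#' `+1` if `delta < d <= gamma`, `0` if `|d| <= delta`, `-1` if
#' `-gamma <= d < -delta`, `-2` if `d < -gamma`. The boundary cases follow
#' these inequalities exactly (`d = gamma` gives +1, `d = delta` gives 0,
#' `d = -gamma` gives -1), with no floating-point fuzz.
#'
#' @param d Numeric vector of differences between consecutive samples
#'   (`d = x_j - x_{j+1}`, earlier minus later).
#' @param params An [slpen_params()] object (only the thresholds are used).
#' @return Integer vector of the same length with values in `-2:2`.
#' @examples
#' slope_symbol(c(1, 0, -0.5, 0.8, -0.8), slpen_params())
#' @export
slope_symbol <- function(d, params = slpen_params()) {
  stopifnot(inherits(params, "slpen_params"))
  if (!is.numeric(d) || !all(is.finite(d)))
    abort("Differences must be finite numbers.", class = "slpen_invalid_input")
  delta <- params$delta
  gamma <- params$gamma
  s <- integer(length(d))
  s[d > gamma] <- 2L
  s[d > delta & d <= gamma] <- 1L
  s[d < -delta & d >= -gamma] <- -1L
  s[d < -gamma] <- -2L
  s
}

# Symbol string of the whole series; window i of length m uses entries
# i..(i + m - 2), so the per-window strings are rolling windows of this.
series_symbols <- function(x, params) {
  d <- x[-length(x)] - x[-1L]  # d_j = x_j - x_{j+1}
  slope_symbol(d, params)
}

#' Symbolic pattern histogram of a time series
#'
#' Extracts all `N - (m - 1)` overlapping subsequences of length `m`,
#' converts each to its length-`(m - 1)` string of slope symbols and counts
#' the distinct strings. The number of distinct strings actually found,
#' `k`, is the quantity Slope Entropy normalises by; it is bounded by
#' `min(N - m + 1, 5^(m-1))` and is typically orders of magnitude below the
#' theoretical `5^(m-1)` because of forbidden patterns.
#'
#' @param x Numeric time series (finite values, `length(x) >= m`).
#' @param params An [slpen_params()] object.
#' @return A tibble of class `slpen_histogram` with columns `pattern`
#'   (symbols joined by commas, e.g. `"0,1,-2"`) and `count`, sorted by
#'   decreasing count; attributes `k`, `n_sub` and `params`.
#' @examples
#' pattern_histogram(c(0, 1, 0, 1, 0, 1), slpen_params(m = 3))
#' @export
pattern_histogram <- function(x, params = slpen_params()) {
  stopifnot(inherits(params, "slpen_params"))
  check_series(x, m = params$m)
  m <- params$m
  if (m - 1L > 22L)  # 5^(m-1) must stay exactly representable as a double
    abort("Embedding dimension too large for exact pattern coding (m <= 23).",
          class = "slpen_invalid_input")
  s <- series_symbols(x, params)
  w <- m - 1L
  n_sub <- length(x) - w
  # stats::embed() yields each length-w window (columns reversed, which is a
  # bijection on strings); encode windows as base-5 integers for counting.
  windows <- stats::embed(s + 2L, w)
  codes <- as.vector(windows %*% 5^(seq_len(w) - 1L))
  counts <- table(codes)
  code_vals <- as.numeric(names(counts))
  pats <- vapply(code_vals, decode_pattern, character(1), width = w)
  out <- tibble::tibble(pattern = pats, count = as.integer(counts))
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$pattern)
  structure(out,
            class = c("slpen_histogram", class(out)),
            k = nrow(out), n_sub = n_sub, params = params)
}

# Invert the base-5 window code back to a "s1,s2,..." string. embed() stores
# windows reversed (latest first), so re-reverse to report in time order.
decode_pattern <- function(code, width) {
  digits <- integer(width)
  for (j in seq_len(width)) {
    digits[j] <- code %% 5
    code <- code %/% 5
  }
  paste(rev(digits) - 2L, collapse = ",")
}

#' Slope Entropy of a time series
#'
#' Computes Slope Entropy (SlpEn): the Shannon-form sum
#' \deqn{\mathrm{SlpEn} = -\sum_{i=1}^{k} p_i \log_2 p_i, \qquad p_i = c_i / k,}
#' where \eqn{c_i} are the symbolic pattern counts of [pattern_histogram()]
#' and \eqn{k} is the number of distinct patterns found. Because the
#' normaliser is `k` rather than the number of subsequences, the \eqn{p_i}
#' do not sum to 1 and the result is not confined to classical entropy
#' ranges: deterministic series give large negative values (down to
#' `-(N - m + 1) * log2(N - m + 1)` for a constant-gradient series) while
#' random series give small positive values. All logarithms are base 2;
#' results are in bits.
#'
#' @inheritParams pattern_histogram
#' @return An object of class `slpen_result`: a list with elements `value`
#'   (bits), `k`, `n_sub`, `params` and `histogram`.
#' @seealso [normalise_slpen()] to rescale the raw value into \[0, 1\],
#'   [slpen_profile()] for the data-frame pipeline over many records.
#' @examples
#' slope_entropy(sin(2 * pi * (0:999) / 100))
#' slope_entropy(rep(1, 66), slpen_params(m = 4, gamma = 0.2))
#' @export
slope_entropy <- function(x, params = slpen_params()) {
  h <- pattern_histogram(x, params)
  k <- attr(h, "k")
  p <- h$count / k
  stopifnot(all(h$count >= 1L))  # 0 * log2(0) cannot arise
  structure(list(value = -sum(p * log2(p)),
                 k = k,
                 n_sub = attr(h, "n_sub"),
                 params = params,
                 histogram = h),
            class = "slpen_result")
}

#' @export
print.slpen_result <- function(x, ...) {
  cat(sprintf("<slpen_result> SlpEn = %.6g bits (k = %d patterns, %d subsequences; m = %d, delta = %g, gamma = %g)\n",
              x$value, x$k, x$n_sub, x$params$m, x$params$delta, x$params$gamma))
  invisible(x)
}

#' @describeIn slope_entropy Pattern histogram of a fitted result as a
#'   tibble with relative frequencies `p = count / k`.
#' @param ... Unused.
#' @method tidy slpen_result
#' @export
tidy.slpen_result <- function(x, ...) {
  h <- x$histogram
  tibble::tibble(pattern = h$pattern, count = h$count, p = h$count / x$k)
}

#' @describeIn slope_entropy One-row summary tibble (`slpen`, `k`, `n_sub`,
#'   `m`, `delta`, `gamma`).
#' @method glance slpen_result
#' @export
glance.slpen_result <- function(x, ...) {
  tibble::tibble(slpen = x$value, k = x$k, n_sub = x$n_sub,
                 m = x$params$m, delta = x$params$delta,
                 gamma = x$params$gamma)
}

#' Slope Entropy of a near-constant series with singleton disturbances
#'
#' Closed-form SlpEn of a constant-gradient series of `n_sub` subsequences
#' in which `k - 1` isolated disturbances have each carved out one new
#' singleton pattern, leaving `n_sub - (k - 1)` matches in the dominant bin:
#' \deqn{-\frac{n-(k-1)}{k}\log_2\frac{n-(k-1)}{k} - (k-1)\frac{1}{k}\log_2\frac{1}{k}.}
#' At `k = 1` this reduces to the exact minimum `-n_sub * log2(n_sub)`.
#' The heuristic lower normalisation bound evaluates this model at one
#' pattern per 100 samples.
#'
#' @param n_sub Number of subsequences, `N - (m - 1)`.
#' @param k Number of distinct patterns, `1 <= k <= n_sub`.
#' @return SlpEn of the model series, in bits (vectorised over `k`).
#' @examples
#' slpen_constant_model(4995, 1)   # -61369.91
#' slpen_constant_model(4995, 10)  # about -4465.3
#' @export
slpen_constant_model <- function(n_sub, k) {
  if (length(n_sub) != 1L || !is.numeric(n_sub) || !is.finite(n_sub) ||
      n_sub != round(n_sub) || n_sub < 1)
    abort("`n_sub` must be a single positive integer.",
          class = "slpen_invalid_input")
  if (!is.numeric(k) || any(!is.finite(k)) || any(k != round(k)) ||
      any(k < 1) || any(k > n_sub))
    abort("`k` must be integer(s) in [1, n_sub].", class = "slpen_invalid_input")
  dominant <- (n_sub - (k - 1)) / k
  -dominant * log2(dominant) - (k - 1) * (1 / k) * log2(1 / k)
}
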