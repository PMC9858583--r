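#' Analytic and heuristic reference bounds for SlpEn normalisation
#'
#' Raw SlpEn values span several orders of magnitude (large negative for
#' deterministic series, small positive for random ones). Max-min
#' normalisation rescales them to \[0, 1\] using a lower and an upper
#' reference value. Three schemes are provided:
#'
#' * `"analytic"` — provable extremes: lower `-N * log2(N)` (constant-gradient
#'   series, simplified from the exact `-(N - m + 1) * log2(N - m + 1)`) and
#'   upper `2 * sqrt(N) / (e * ln 2)` (uniform histogram at its maximising
#'   pattern count `k* = e * sqrt(N)`). Never violated, but so conservative
#'   that real signals crowd into 0.9-1.0.
#' * `"recommended"` — the mixed scheme: heuristic lower bound (the
#'   [slpen_constant_model()] evaluated at one pattern per
#'   `samples_per_pattern` samples, default 100) with the analytic upper
#'   bound. Deterministic series fall below the lower bound and clip to 0;
#'   real signals spread over the interval. This is the default.
#' * `"heuristic"` — heuristic lower bound plus a heuristic upper bound from
#'   a regression estimate of the pattern count as a function of `m`
#'   (see [fit_k_model()]); requires `fit`.
#'
#' Bounds are per record: `n` is each record's own length.
#'
#' @param n Series length `N` (number of samples).
#' @param m Embedding dimension (used by the heuristic bounds).
#' @param scheme One of `"recommended"`, `"analytic"`, `"heuristic"`.
#' @param samples_per_pattern Samples per additional pattern assumed by the
#'   heuristic lower bound; the assumed pattern count is
#'   `k_h = max(1, round(n / samples_per_pattern))`.
#' @param fit An `slpen_kfit` regression of pattern count on `m`
#'   (only for `scheme = "heuristic"`).
#' @return A list of class `slpen_bounds`: `lower`, `upper` (bits), `scheme`,
#'   `k_lower`, `k_upper` (pattern counts each bound assumes).
#' @examples
#' slpen_bounds(5000)                        # recommended: (-650.1, 75.06)
#' slpen_bounds(5000, scheme = "analytic")   # (-61438.6, 75.06)
#' @export
slpen_bounds <- function(n, m = 6,
                         scheme = c("recommended", "analytic", "heuristic"),
                         samples_per_pattern = 100, fit = NULL) {
  scheme <- match.arg(scheme)
  check_length(n)
  if (scheme == "analytic") {
    lower <- slpen_analytic_min(n)
    k_lower <- 1L
  } else {
    lower <- slpen_heuristic_min(n, m, samples_per_pattern)
    k_lower <- k_heuristic(n, samples_per_pattern)
  }
  if (scheme == "heuristic") {
    if (is.null(fit))
      abort("`scheme = \"heuristic\"` requires a pattern-count regression `fit`.",
            class = "slpen_invalid_configuration")
    upper <- slpen_heuristic_max(n, m, fit)
    k_upper <- khat_capped(n, m, fit)
  } else {
    upper <- slpen_analytic_max(n)
    k_upper <- round(slpen_kstar(n))
  }
  if (upper <= lower)
    abort("Degenerate bounds: upper <= lower.", class = "slpen_invalid_bounds")
  structure(list(lower = lower, upper = upper, scheme = scheme,
                 k_lower = k_lower, k_upper = k_upper),
            class = "slpen_bounds")
}

#' @export
print.slpen_bounds <- function(x, ...) {
  cat(sprintf("<slpen_bounds> scheme = %s: [%.4f, %.4f] bits (k_lower = %d, k_upper = %d)\n",
              x$scheme, x$lower, x$upper, x$k_lower, x$k_upper))
  invisible(x)
}

check_length <- function(n, min = 2) {
  if (length(n) != 1L || !is.numeric(n) || !is.finite(n) ||
      n != round(n) || n < min)
    abort(sprintf("Series length must be a single integer >= %d.", min),
          class = "slpen_invalid_input")
  invisible(n)
}

#' Analytic SlpEn extremes
#'
#' `slpen_analytic_min()` is the simplified lower bound `-N * log2(N)` used
#' in the normalisation denominator; `slpen_exact_min()` is the exact
#' minimum `-n_sub * log2(n_sub)` attained by any constant-gradient series
#' with `n_sub = N - (m - 1)` subsequences. `slpen_kstar()` is the
#' continuous pattern count `e * sqrt(N)` maximising the uniform-histogram
#' expression `f(k) = (N / k) * log2(k^2 / N)`, and `slpen_analytic_max()`
#' is that expression at its maximiser, `2 * sqrt(N) / (e * ln 2)` — the
#' base-2 value consistent with SlpEn measured in bits. No raw SlpEn can
#' fall outside `[slpen_exact_min(n_sub), slpen_analytic_max(N)]`.
#'
#' @param n Series length `N`, at least 2.
#' @param n_sub Subsequence count `N - (m - 1)`, at least 1.
#' @return A length-1 numeric (bits; `slpen_kstar()` is in patterns).
#' @examples
#' slpen_analytic_min(5000)   # -61438.56
#' slpen_exact_min(4995)      # -61369.91
#' slpen_kstar(5000)          # 192.21
#' slpen_analytic_max(5000)   # 75.06
#' @export
slpen_analytic_min <- function(n) {
  check_length(n)
  -n * log2(n)
}

#' @rdname slpen_analytic_min
#' @export
slpen_exact_min <- function(n_sub) {
  check_length(n_sub, min = 1)
  -n_sub * log2(n_sub)
}

#' @rdname slpen_analytic_min
#' @export
slpen_kstar <- function(n) {
  check_length(n)
  exp(1) * sqrt(n)
}

#' @rdname slpen_analytic_min
#' @export
slpen_analytic_max <- function(n) {
  check_length(n)
  2 * sqrt(n) / (exp(1) * log(2))
}

# Uniform-histogram SlpEn at pattern count k (bits).
uniform_slpen <- function(n, k) (n / k) * log2(k^2 / n)

k_heuristic <- function(n, samples_per_pattern) {
  if (length(samples_per_pattern) != 1L || !is.numeric(samples_per_pattern) ||
      !is.finite(samples_per_pattern) || samples_per_pattern < 1)
    abort("`samples_per_pattern` must be a single number >= 1.",
          class = "slpen_invalid_input")
  max(1L, as.integer(round(n / samples_per_pattern)))
}

#' Heuristic lower normalisation bound
#'
#' Evaluates the near-constant-series model [slpen_constant_model()] with
#' one singleton pattern per `samples_per_pattern` samples,
#' `k_h = max(1, round(n / samples_per_pattern))`, on the record's
#' `n_sub = n - (m - 1)` subsequences. Series more deterministic than this
#' model (constant, constant-gradient, pure sinusoids) fall below the bound
#' and are clipped to a normalised value of exactly 0.
#'
#' @inheritParams slpen_bounds
#' @return Lower bound in bits.
#' @examples
#' slpen_heuristic_min(5000, 6)   # about -650.1 (k_h = 50)
#' @export
slpen_heuristic_min <- function(n, m = 6, samples_per_pattern = 100) {
  check_length(n, min = m)
  k_h <- k_heuristic(n, samples_per_pattern)
  slpen_constant_model(n - (m - 1), min(k_h, n - (m - 1)))
}

khat_capped <- function(n, m, fit) {
  khat <- round(predict_k(fit, m))
  khat <- min(khat, 5^(m - 1), n - (m - 1))
  if (khat < 2)
    abort("Regression predicts fewer than 2 patterns; heuristic upper bound undefined.",
          class = "slpen_invalid_configuration")
  as.integer(khat)
}

#' Heuristic upper normalisation bound
#'
#' Replaces the analytic maximiser `k* = e * sqrt(n)` with a regression
#' estimate of the pattern count expected at embedding dimension `m`
#' (capped at the theoretical `5^(m-1)` and at the subsequence count), and
#' evaluates the uniform-histogram expression `(n / k) * log2(k^2 / n)`
#' there. Because the expression is maximised at `k*`, this bound is at
#' most [slpen_analytic_max()].
#'
#' @inheritParams slpen_bounds
#' @param fit An `slpen_kfit` object from [fit_k_model()].
#' @return Upper bound in bits.
#' @examples
#' fit <- fit_k_model(k_observations(), family = "power")
#' slpen_heuristic_max(5000, 6, fit)   # about 48.6 (k-hat ~ 665)
#' @export
slpen_heuristic_max <- function(n, m, fit) {
  check_length(n, min = m)
  uniform_slpen(n, khat_capped(n, m, fit))
}

#' Recommended normalisation bounds
#'
#' The mixed scheme: heuristic lower bound with the analytic upper bound.
#' Shorthand for `slpen_bounds(n, m, scheme = "recommended")`.
#'
#' @inheritParams slpen_bounds
#' @return An `slpen_bounds` object.
#' @export
recommended_bounds <- function(n, m = 6, samples_per_pattern = 100) {
  slpen_bounds(n, m, scheme = "recommended",
               samples_per_pattern = samples_per_pattern)
}

#' Max-min normalisation of raw SlpEn values
#'
#' Rescales raw SlpEn values to `(raw - lower) / (upper - lower)`. Values
#' below the lower bound (possible under the heuristic/recommended schemes,
#' by design, for deterministic series) are clipped to 0. Under the
#' analytic and recommended schemes the upper bound is provable, so values
#' cannot exceed 1; under the fully heuristic scheme a value above 1 is
#' capped defensively with a warning.
#'
#' @param raw Numeric vector of raw SlpEn values (bits).
#' @param bounds An `slpen_bounds` object from [slpen_bounds()].
#' @return A tibble with columns `raw`, `normalised` (in \[0, 1\]) and
#'   `clipped` (`TRUE` where `raw < lower`).
#' @examples
#' b <- slpen_bounds(5000, scheme = "analytic")
#' normalise_slpen(c(-61438.56, 39.8, 75.06), b)
#' @export
normalise_slpen <- function(raw, bounds) {
  if (!inherits(bounds, "slpen_bounds"))
    abort("`bounds` must be an <slpen_bounds> object.",
          class = "slpen_invalid_input")
  if (!is.numeric(raw) || any(!is.finite(raw)))
    abort("`raw` must be finite numeric.", class = "slpen_invalid_input")
  z <- (raw - bounds$lower) / (bounds$upper - bounds$lower)
  clipped <- z < 0
  z[clipped] <- 0
  if (any(z > 1)) {
    warn("Normalised SlpEn above 1 under a heuristic upper bound; capping at 1.")
    z[z > 1] <- 1
  }
  tibble::tibble(raw = raw, normalised = z, clipped = clipped)
}
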