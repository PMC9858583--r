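#' Seeded synthetic time-series generators
#'
#' Generates the benchmark signal families used to characterise SlpEn and
#' its normalisation bounds. Each call returns a tibble with one row per
#' record and the samples in a list-column, ready for [slpen_profile()].
#'
#' Kinds and their parameters (passed via `...`):
#' * `"constant"` — every sample equals `level` (default 1).
#' * `"constant_gradient"` — `x0 + (0:(n-1)) * step` (default `x0 = 0`,
#'   `step = 0.1`); always yields a single slope pattern (`k = 1`)
#'   whatever the thresholds.
#' * `"constant_with_outlier"` — constant `level` with one sample at an
#'   interior `position` (default `floor(n/2)`) replaced by `outlier`
#'   (default `level + 1`); one outlier carves out `m` extra patterns.
#' * `"sinusoid"` — `amplitude * sin(2*pi*t/period + phase)` at unit-spaced
#'   `t`, `phase` drawn uniformly on \[0, 2*pi) per record (defaults
#'   `period = 100`, `amplitude = 1`). Consecutive differences are bounded
#'   by `2 * amplitude * sin(pi / period)`.
#' * `"gaussian"` — i.i.d. normal samples (`mean = 0`, `sd = 1`).
#' * `"uniform"` — i.i.d. uniform samples; default `min = -sqrt(3)`,
#'   `max = sqrt(3)`, i.e. zero mean and unit variance so the two random
#'   classes are amplitude-comparable.
#'
#' @param kind Signal family (see above).
#' @param n Record length `N` (samples), at least 2.
#' @param n_records Number of records to generate.
#' @param seed Integer seed; the output is bit-identical for a fixed seed.
#' @param class Class label attached to every record (default `NA`).
#' @param ... Kind-specific parameters, see above.
#' @return A tibble with columns `series_id` (character), `kind`, `class`,
#'   `n`, and `series` (list of numeric vectors).
#' @examples
#' simulate_series("sinusoid", n = 500, n_records = 2, seed = 7, period = 50)
#' @export
simulate_series <- function(kind = c("constant", "constant_gradient",
                                     "constant_with_outlier", "sinusoid",
                                     "gaussian", "uniform"),
                            n = 5000, n_records = 1, seed = NULL,
                            class = NA_integer_, ...) {
  kind <- tryCatch(match.arg(kind), error = function(e)
    abort(sprintf("Unknown signal kind '%s'.", kind[1]),
          class = "slpen_configuration_error"))
  check_length(n)
  if (n_records < 1) abort("`n_records` must be >= 1.",
                           class = "slpen_configuration_error")
  if (!is.null(seed)) set.seed(seed)
  opts <- list(...)
  gen <- switch(kind,
    constant = function() rep(opts$level %||% 1, n),
    constant_gradient = function() {
      (opts$x0 %||% 0) + (0:(n - 1)) * (opts$step %||% 0.1)
    },
    constant_with_outlier = function() {
      level <- opts$level %||% 1
      pos <- opts$position %||% (n %/% 2)
      if (pos <= 1 || pos >= n)
        abort("Outlier `position` must be interior (1 < position < n).",
              class = "slpen_configuration_error")
      x <- rep(level, n)
      x[pos] <- opts$outlier %||% (level + 1)
      x
    },
    sinusoid = function() {
      period <- opts$period %||% 100
      amplitude <- opts$amplitude %||% 1
      phase <- runif(1, 0, 2 * pi)
      amplitude * sin(2 * pi * (0:(n - 1)) / period + phase)
    },
    gaussian = function() rnorm(n, opts$mean %||% 0, opts$sd %||% 1),
    uniform = function() runif(n, opts$min %||% -sqrt(3), opts$max %||% sqrt(3))
  )
  tibble::tibble(
    series_id = sprintf("%s_%03d", kind, seq_len(n_records)),
    kind = kind,
    class = rep(class, n_records),
    n = as.integer(n),
    series = replicate(n_records, gen(), simplify = FALSE)
  )
}

#' Two-class benchmark datasets
#'
#' `slpen_random_dataset()` draws the Random benchmark: `n_per_class`
#' standard-normal records (Class 0) and `n_per_class` zero-mean
#' unit-variance uniform records (Class 1), each of length `n`.
#' `slpen_periodic_dataset()` draws the Periodic benchmark: `n_per_class`
#' sinusoids of period 100 samples (Class 0) and `n_per_class` of period
#' 500 (Class 1), unit amplitude, random phase. The Random pair probes pure
#' randomness (SlpEn near its upper bound); the Periodic pair is purely
#' deterministic (large negative SlpEn that the recommended scheme clips
#' to 0).
#'
#' @param n_per_class Records per class (default 100).
#' @param n Record length (default 5000).
#' @param seed Integer seed for reproducibility.
#' @return A tibble as in [simulate_series()], with `class` 0/1.
#' @examples
#' head(slpen_random_dataset(n_per_class = 2, n = 100, seed = 1))
#' @export
slpen_random_dataset <- function(n_per_class = 100, n = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dplyr::bind_rows(
    simulate_series("gaussian", n = n, n_records = n_per_class, class = 0L),
    simulate_series("uniform", n = n, n_records = n_per_class, class = 1L)
  )
}

#' @rdname slpen_random_dataset
#' @export
slpen_periodic_dataset <- function(n_per_class = 100, n = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- dplyr::bind_rows(
    simulate_series("sinusoid", n = n, n_records = n_per_class,
                    class = 0L, period = 100),
    simulate_series("sinusoid", n = n, n_records = n_per_class,
                    class = 1L, period = 500)
  )
  out$series_id <- sprintf("sinusoid_T%d_%03d",
                           rep(c(100L, 500L), each = n_per_class),
                           rep(seq_len(n_per_class), 2))
  out
}

#' Shorten a time series by truncation or decimation
#'
#' `truncate_series()` keeps the leading `length` samples;
#' `decimate_series()` keeps every `rate`-th sample starting at the first
#' (rate 1 is the identity). Both are the standard ways of probing SlpEn
#' behaviour on short records.
#'
#' @param x Numeric time series.
#' @param length Number of leading samples to keep.
#' @param rate Integer decimation rate, >= 1.
#' @return The shortened numeric series.
#' @examples
#' truncate_series(1:10, 4)
#' decimate_series(1:10, 5)
#' @export
truncate_series <- function(x, length) {
  check_series(x)
  if (length < 1 || length > base::length(x))
    abort("Truncation length must be in [1, length(x)].",
          class = "slpen_invalid_input")
  x[seq_len(length)]
}

#' @rdname truncate_series
#' @export
decimate_series <- function(x, rate) {
  check_series(x)
  if (length(rate) != 1L || rate < 1 || rate != round(rate))
    abort("`rate` must be a single integer >= 1.",
          class = "slpen_invalid_input")
  out <- x[seq(1L, length(x), by = rate)]
  if (length(out) < 1)
    abort("Decimation produced an empty series.", class = "slpen_invalid_input")
  out
}
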