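#' SlpEn profile of a dataset of records
#'
#' The data-frame pipeline: takes a tibble of records (as produced by
#' [simulate_series()] and friends, with the samples of each record in a
#' list-column), computes raw Slope Entropy per record, and — unless
#' `scheme = "none"` — normalises each value with per-record bounds (each
#' record's own length sets its bounds, so mixed-length datasets are
#' handled correctly).
#'
#' @param data A data frame with a list-column of numeric series.
#' @param series Name of the list-column holding the samples
#'   (default `"series"`).
#' @param params An [slpen_params()] object.
#' @param scheme `"none"` for raw SlpEn only, otherwise passed to
#'   [slpen_bounds()] (`"recommended"`, `"analytic"`, `"heuristic"`).
#' @param samples_per_pattern,fit Passed to [slpen_bounds()].
#' @return The input tibble without the list-column, with added columns
#'   `n`, `slpen` (raw bits), `k`, `n_sub`, and when normalising also
#'   `lower`, `upper`, `normalised`, `clipped`.
#' @examples
#' slpen_random_dataset(n_per_class = 3, n = 1000, seed = 1) |>
#'   slpen_profile(scheme = "analytic")
#' @export
slpen_profile <- function(data, series = "series", params = slpen_params(),
                          scheme = c("recommended", "analytic",
                                     "heuristic", "none"),
                          samples_per_pattern = 100, fit = NULL) {
  scheme <- match.arg(scheme)
  if (!is.data.frame(data) || !series %in% names(data))
    abort(sprintf("`data` must be a data frame with a '%s' list-column.",
                  series), class = "slpen_invalid_input")
  xs <- data[[series]]
  if (!is.list(xs))
    abort(sprintf("Column '%s' must be a list of numeric vectors.", series),
          class = "slpen_invalid_input")
  res <- purrr::map(xs, function(x) {
    r <- slope_entropy(x, params)
    tibble::tibble(n = length(x), slpen = r$value, k = r$k, n_sub = r$n_sub)
  })
  meta <- dplyr::select(tibble::as_tibble(data), -dplyr::all_of(series))
  meta <- dplyr::select(meta, -dplyr::any_of(c("n", "slpen", "k", "n_sub",
                                               "lower", "upper",
                                               "normalised", "clipped")))
  out <- dplyr::bind_cols(meta, dplyr::bind_rows(res))
  if (scheme != "none") {
    norm <- purrr::map2(out$slpen, out$n, function(raw, n) {
      b <- slpen_bounds(n, m = params$m, scheme = scheme,
                        samples_per_pattern = samples_per_pattern, fit = fit)
      v <- normalise_slpen(raw, b)
      tibble::tibble(lower = b$lower, upper = b$upper,
                     normalised = v$normalised, clipped = v$clipped)
    })
    out <- dplyr::bind_cols(out, dplyr::bind_rows(norm))
  }
  class(out) <- c("slpen_tbl", class(out))
  out
}
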