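#' Single-feature threshold classification
#'
#' Exhaustive single-threshold classifier on one feature: every midpoint of
#' consecutive sorted unique feature values is tried with both polarities
#' (low values positive, or high values positive), and the rule maximising
#' resubstitution accuracy is kept; ties are broken toward higher
#' sensitivity. Class 0 is the positive class, so sensitivity is the
#' true-positive rate on Class 0 records and specificity the true-negative
#' rate on Class 1. Any strictly increasing transformation of the feature
#' yields the same sensitivity and specificity, which is the property that
#' makes max-min normalisation classification-neutral.
#'
#' @param data A data frame of labelled feature values.
#' @param value Column with the feature (tidy-eval; default `slpen`).
#' @param class Column with the class labels 0/1 (tidy-eval;
#'   default `class`).
#' @return A one-row tibble of class `slpen_classification`: `sensitivity`,
#'   `specificity`, `accuracy`, `threshold`, `direction` (`"low"` if values
#'   below the threshold are called Class 0), and the class sizes.
#' @examples
#' d <- tibble::tibble(class = rep(0:1, each = 5),
#'                     slpen = c(rnorm(5, -2), rnorm(5, 2)))
#' threshold_classify(d)
#' @export
threshold_classify <- function(data, value = "slpen", class = "class") {
  v <- dplyr::pull(data, {{ value }})
  cl <- dplyr::pull(data, {{ class }})
  if (!is.numeric(v) || any(!is.finite(v)))
    abort("Feature values must be finite numeric.", class = "slpen_invalid_input")
  cl <- as.integer(cl)
  if (!all(cl %in% c(0L, 1L)))
    abort("Class labels must be 0 or 1 (0 = positive class).",
          class = "slpen_invalid_input")
  n0 <- sum(cl == 0L); n1 <- sum(cl == 1L)
  if (n0 == 0L || n1 == 0L)
    abort("Both classes must be non-empty.", class = "slpen_invalid_input")
  u <- sort(unique(v))
  cuts <- if (length(u) == 1L) u else (u[-length(u)] + u[-1L]) / 2
  cuts <- c(u[1] - 1, cuts, u[length(u)] + 1)  # all-one-class rules included
  best <- NULL
  for (dir in c("low", "high")) {
    for (thr in cuts) {
      pred0 <- if (dir == "low") v <= thr else v > thr
      sens <- sum(pred0 & cl == 0L) / n0
      spec <- sum(!pred0 & cl == 1L) / n1
      acc <- (sens * n0 + spec * n1) / (n0 + n1)
      cand <- list(acc = acc, sens = sens, spec = spec,
                   thr = thr, dir = dir)
      if (is.null(best) || acc > best$acc ||
          (acc == best$acc && sens > best$sens))
        best <- cand
    }
  }
  out <- tibble::tibble(sensitivity = best$sens, specificity = best$spec,
                        accuracy = best$acc, threshold = best$thr,
                        direction = best$dir, n_class0 = n0, n_class1 = n1)
  class(out) <- c("slpen_classification", class(out))
  out
}

#' Does normalisation leave classification unchanged?
#'
#' Runs [threshold_classify()] on a raw feature and on its normalised
#' counterpart and reports whether sensitivity and specificity are
#' identical. They must be whenever the normalisation is strictly
#' increasing over the observed values (no record clipped); when the
#' heuristic lower bound clips a whole class to 0, invariance is expected
#' to break — which is the paper trail a user should look for.
#'
#' @param data A data frame with raw and normalised feature columns and a
#'   class column.
#' @param raw,normalised,class Tidy-eval column names (defaults `slpen`,
#'   `normalised`, `class`).
#' @return A list of class `slpen_invariance`: `invariant` (logical),
#'   `raw` and `normalised` classification reports.
#' @examples
#' d <- slpen_random_dataset(2, n = 500, seed = 3) |>
#'   slpen_profile(scheme = "analytic")
#' invariance_check(d)
#' @export
invariance_check <- function(data, raw = "slpen", normalised = "normalised",
                             class = "class") {
  rep_raw <- threshold_classify(data, {{ raw }}, {{ class }})
  rep_norm <- threshold_classify(data, {{ normalised }}, {{ class }})
  structure(list(
    invariant = isTRUE(rep_raw$sensitivity == rep_norm$sensitivity &&
                       rep_raw$specificity == rep_norm$specificity),
    raw = rep_raw, normalised = rep_norm),
    class = "slpen_invariance")
}

#' @export
print.slpen_invariance <- function(x, ...) {
  cat(sprintf("<slpen_invariance> invariant: %s\n", x$invariant))
  cat(sprintf("  raw:        sens %.3f, spec %.3f\n",
              x$raw$sensitivity, x$raw$specificity))
  cat(sprintf("  normalised: sens %.3f, spec %.3f\n",
              x$normalised$sensitivity, x$normalised$specificity))
  invisible(x)
}

#' Grid search over SlpEn parameters for classification accuracy
#'
#' Optional tuning helper: evaluates [threshold_classify()] accuracy of raw
#' SlpEn over a small grid of `(m, delta, gamma)` and returns the grid
#' sorted by accuracy.
#'
#' @param data A record tibble as accepted by [slpen_profile()].
#' @param m,delta,gamma Vectors defining the grid.
#' @param series Name of the series list-column.
#' @return A tibble with one row per grid point: `m`, `delta`, `gamma`,
#'   `sensitivity`, `specificity`, `accuracy`, sorted best-first.
#' @export
tune_slpen <- function(data, m = 3:9, delta = c(1e-3, 1e-2),
                       gamma = seq(0.2, 1.0, by = 0.2), series = "series") {
  grid <- tidyr_expand_grid(m = m, delta = delta, gamma = gamma)
  res <- purrr::pmap(grid, function(m, delta, gamma) {
    prof <- slpen_profile(data, series = series,
                          params = slpen_params(m, delta, gamma),
                          scheme = "none")
    rep <- threshold_classify(prof)
    tibble::tibble(m = m, delta = delta, gamma = gamma,
                   sensitivity = rep$sensitivity,
                   specificity = rep$specificity, accuracy = rep$accuracy)
  })
  dplyr::arrange(dplyr::bind_rows(res), dplyr::desc(.data$accuracy))
}

# expand.grid with tibble output, deterministic column order
tidyr_expand_grid <- function(...) {
  tibble::as_tibble(expand.grid(..., KEEP.OUT.ATTRS = FALSE))
}
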