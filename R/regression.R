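#' Reference pattern-count observations for random series
#'
#' Maximum number of distinct slope patterns (`k_max`) observed across 100
#' random time series of length 5000, for embedding dimensions `m` = 3..9.
#' These are the reference observations behind the heuristic upper bound:
#' the observed counts sit orders of magnitude below the theoretical
#' `5^(m-1)`, and their growth with `m` is what [fit_k_model()] models.
#'
#' @param path Optional path to a two-column CSV (`m`, `k_max`) to load
#'   instead of the packaged reference table.
#' @return A tibble with integer columns `m` and `k_max`.
#' @examples
#' k_observations()
#' @export
k_observations <- function(path = NULL) {
  path <- path %||% system.file("extdata", "kmax_random_n5000.csv",
                                package = "slpen", mustWork = TRUE)
  df <- utils::read.csv(path)
  if (!all(c("m", "k_max") %in% names(df)))
    abort("Observation file must have columns `m` and `k_max`.",
          class = "slpen_format_error")
  if (any(df$k_max < 1) || any(df$k_max > 5^(df$m - 1)))
    abort("k_max values must lie in [1, 5^(m-1)].",
          class = "slpen_invalid_input")
  tibble::tibble(m = as.integer(df$m), k_max = as.integer(df$k_max))
}

kfit_ncoef <- c(linear = 2L, quadratic = 3L, cubic = 4L, power = 2L)

#' Fit a pattern-count growth model k(m)
#'
#' Fits one of four regression families to observed (embedding dimension,
#' maximum pattern count) pairs: `linear`, `quadratic` and `cubic`
#' polynomials by ordinary least squares on `(m, k)`, and `power`
#' (`k = a * m^b`) by ordinary least squares of `log k` on `log m` with
#' `a = exp(intercept)`, `b = slope`. The reported correlation `r` is the
#' Pearson correlation between observed and fitted pattern counts (for the
#' linear family this equals the Pearson correlation of the raw pairs).
#'
#' @param observations A data frame with columns `m` and `k_max`
#'   (default: the packaged [k_observations()]).
#' @param family One of `"linear"`, `"quadratic"`, `"cubic"`, `"power"`.
#' @return An object of class `slpen_kfit`: list with `family`,
#'   `coefficients` (increasing powers for polynomials; `c(a, b)` for
#'   power), `r`, and the `observations` used.
#' @examples
#' fit_k_model(family = "power")
#' fit_k_model(family = "linear")
#' @export
fit_k_model <- function(observations = k_observations(),
                        family = c("power", "linear", "quadratic", "cubic")) {
  family <- match.arg(family)
  obs <- tibble::as_tibble(observations)
  if (!all(c("m", "k_max") %in% names(obs)))
    abort("`observations` needs columns `m` and `k_max`.",
          class = "slpen_invalid_input")
  m <- as.numeric(obs$m)
  k <- as.numeric(obs$k_max)
  need <- kfit_ncoef[[family]]
  if (length(m) < need)
    abort(sprintf("Family '%s' needs at least %d observations.", family, need),
          class = "slpen_invalid_input")
  if (family == "power" && any(k <= 0))
    abort("Power fits require strictly positive pattern counts.",
          class = "slpen_invalid_input")
  fit_ols <- function(formula, data) {
    f <- tryCatch(lm(formula, data = data), error = function(e)
      abort("Singular fit.", class = "slpen_singular_fit"))
    if (anyNA(coef(f)))
      abort("Degenerate design matrix (collinear observations).",
            class = "slpen_singular_fit")
    f
  }
  dat <- data.frame(m = m, k = k)
  coefs <- switch(family,
    linear    = coef(fit_ols(k ~ m, dat)),
    quadratic = coef(fit_ols(k ~ m + I(m^2), dat)),
    cubic     = coef(fit_ols(k ~ m + I(m^2) + I(m^3), dat)),
    power     = {
      f <- fit_ols(log(k) ~ log(m), dat)
      c(a = unname(exp(coef(f)[1])), b = unname(coef(f)[2]))
    })
  fit <- structure(list(family = family,
                        coefficients = unname(coefs),
                        observations = tibble::tibble(m = m, k_max = k)),
                   class = "slpen_kfit")
  fitted_k <- predict_k(fit, m)
  fit$r <- if (stats::sd(fitted_k) == 0 || stats::sd(k) == 0) NA_real_
           else stats::cor(fitted_k, k)
  fit
}

#' Predict the pattern count at an embedding dimension
#'
#' Evaluates a fitted [fit_k_model()] family at `m`. The raw prediction can
#' be out of range (polynomial fits extrapolate to negative counts at small
#' `m`); when used for the heuristic upper bound it is clamped downstream
#' to `[2, min(5^(m-1), n_sub)]`.
#'
#' @param fit An `slpen_kfit` object.
#' @param m Embedding dimension(s), `m >= 3`.
#' @return Numeric vector of predicted pattern counts (unclamped).
#' @examples
#' predict_k(fit_k_model(family = "power"), 6)   # about 665
#' @export
predict_k <- function(fit, m) {
  if (!inherits(fit, "slpen_kfit"))
    abort("`fit` must be an <slpen_kfit> object.", class = "slpen_invalid_input")
  cf <- fit$coefficients
  if (fit$family == "power") cf[1] * m^cf[2]
  else drop(outer(m, seq_along(cf) - 1, `^`) %*% cf)
}

#' @export
predict.slpen_kfit <- function(object, m, ...) predict_k(object, m)

#' @export
print.slpen_kfit <- function(x, ...) {
  eq <- if (x$family == "power")
    sprintf("k = %.4f * m^%.4f", x$coefficients[1], x$coefficients[2])
  else paste0("k = ", paste(sprintf("%.4f*m^%d", x$coefficients,
                                    seq_along(x$coefficients) - 1),
                            collapse = " + "))
  cat(sprintf("<slpen_kfit> %s fit: %s (r = %.4f, n = %d)\n",
              x$family, eq, x$r, nrow(x$observations)))
  invisible(x)
}

#' @describeIn fit_k_model Coefficients as a tibble (`term`, `estimate`).
#' @param x An `slpen_kfit` object.
#' @param ... Unused.
#' @method tidy slpen_kfit
#' @export
tidy.slpen_kfit <- function(x, ...) {
  terms <- if (x$family == "power") c("a", "b")
           else paste0("m^", seq_along(x$coefficients) - 1)
  tibble::tibble(term = terms, estimate = x$coefficients)
}

#' @describeIn fit_k_model One-row fit summary (`family`, `r`, `n_obs`).
#' @method glance slpen_kfit
#' @export
glance.slpen_kfit <- function(x, ...) {
  tibble::tibble(family = x$family, r = x$r, n_obs = nrow(x$observations))
}
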