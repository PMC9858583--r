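#' Plot methods for slpen objects
#'
#' * `autoplot.slpen_result()` — bar chart of the pattern histogram
#'   (top `max_patterns` patterns by count).
#' * `autoplot.slpen_tbl()` — distribution of per-record SlpEn by class
#'   (normalised values when present, raw otherwise).
#' * `autoplot.slpen_kfit()` — observed pattern counts with the fitted
#'   k(m) curve.
#' * `plot_constant_model()` — how SlpEn of a near-constant series rises
#'   as singleton patterns are added, with optional normalisation bounds
#'   overlaid.
#'
#' @param object The object to plot.
#' @param max_patterns Number of patterns to show (histogram plot).
#' @param ... Unused.
#' @return A ggplot object.
#' @name slpen-plots
NULL

#' @rdname slpen-plots
#' @method autoplot slpen_result
#' @export
autoplot.slpen_result <- function(object, max_patterns = 20, ...) {
  d <- utils::head(tidy(object), max_patterns)
  d$pattern <- factor(d$pattern, levels = rev(d$pattern))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$pattern)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "count", y = "slope pattern",
      title = sprintf("SlpEn = %.4g bits, k = %d of %d subsequences",
                      object$value, object$k, object$n_sub)) +
    ggplot2::theme_minimal()
}

#' @rdname slpen-plots
#' @method autoplot slpen_tbl
#' @export
autoplot.slpen_tbl <- function(object, ...) {
  value_col <- if ("normalised" %in% names(object)) "normalised" else "slpen"
  d <- dplyr::mutate(tibble::as_tibble(object),
                     class = factor(.data$class))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[value_col]],
                                  fill = .data$class)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7,
                            position = "identity") +
    ggplot2::labs(x = paste0(value_col, " SlpEn"), y = "records") +
    ggplot2::theme_minimal()
}

#' @rdname slpen-plots
#' @method autoplot slpen_kfit
#' @export
autoplot.slpen_kfit <- function(object, ...) {
  obs <- object$observations
  grid <- tibble::tibble(m = seq(min(obs$m), max(obs$m), length.out = 200))
  grid$k <- predict_k(object, grid$m)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$m, y = .data$k_max)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$k),
                       colour = "firebrick") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "embedding dimension m", y = "max patterns found k",
                  title = sprintf("%s fit, r = %.4f", object$family,
                                  object$r)) +
    ggplot2::theme_minimal()
}

#' @rdname slpen-plots
#' @param n_sub Subsequence count of the modelled series.
#' @param k_range Pattern counts to evaluate.
#' @param bounds Optional `slpen_bounds` to overlay as horizontal lines.
#' @export
plot_constant_model <- function(n_sub = 4995, k_range = 1:50,
                                bounds = NULL) {
  d <- tibble::tibble(k = k_range,
                      slpen = slpen_constant_model(n_sub, k_range))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$slpen)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "patterns k", y = "SlpEn (bits)",
                  title = sprintf("Near-constant series model, %d subsequences",
                                  n_sub)) +
    ggplot2::theme_minimal()
  if (!is.null(bounds))
    p <- p + ggplot2::geom_hline(yintercept = c(bounds$lower, bounds$upper),
                                 linetype = "dashed", colour = "firebrick")
  p
}
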