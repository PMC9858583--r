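#' Read and write univariate time series files
#'
#' `read_series()` reads a univariate series from plain text (one sample
#' per line) or a single-column CSV with an optional header line. Blank
#' lines are skipped; NaN, infinite or unparseable entries raise a format
#' error naming the offending line. `write_series()` writes one sample per
#' line at full double precision (17 significant digits), so a
#' write-then-read round trip reproduces the samples exactly.
#'
#' @param path File path.
#' @return `read_series()`: a numeric vector in file order.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_series(c(1, 2, 3.5), f)
#' read_series(f)
#' @export
read_series <- function(path) {
  if (!file.exists(path))
    abort(sprintf("File not found: %s", path), class = "slpen_format_error")
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*$", lines))
  vals <- trimws(lines[keep])
  # single-column CSV tolerates one trailing comma; a header line may lead
  vals <- sub(",\\s*$", "", vals)
  start <- 1L
  looks_numeric <- function(v)  # NaN parses to NA but is data, not a header
    !is.na(suppressWarnings(as.numeric(v))) || grepl("nan", v, ignore.case = TRUE)
  if (length(vals) >= 1L && !looks_numeric(vals[1]))
    start <- 2L  # header
  if (length(vals) < start)
    abort(sprintf("No samples found in %s.", path), class = "slpen_format_error")
  idx <- seq(start, length(vals))
  x <- suppressWarnings(as.numeric(vals[idx]))
  bad <- which(is.na(x) | !is.finite(x))
  if (length(bad) > 0)
    abort(sprintf("Cannot parse '%s' as a finite sample at line %d of %s.",
                  vals[idx[bad[1]]], keep[idx[bad[1]]], path),
          class = "slpen_format_error")
  x
}

#' @rdname read_series
#' @param x Numeric series to write.
#' @export
write_series <- function(x, path) {
  check_series(x)
  writeLines(sprintf("%.17g", x), path)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Writes each record of a [simulate_series()]-style tibble as a
#' plain-text series file plus a `labels.csv` manifest (`filename,class`).
#'
#' @param data Record tibble with `series_id`, `class` and `series` columns.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(data$series_id, ".txt")
  purrr::walk2(data$series, files,
               function(x, f) write_series(x, file.path(dir, f)))
  manifest <- tibble::tibble(filename = files, class = data$class)
  utils::write.csv(manifest, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing series files and a `labels.csv`
#'   manifest.
#' @return A record tibble with `series_id`, `class`, `n` and `series`
#'   columns, suitable for [slpen_profile()].
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "labels.csv")
  if (!file.exists(manifest_path))
    abort(sprintf("No labels.csv manifest in %s.", dir),
          class = "slpen_format_error")
  manifest <- utils::read.csv(manifest_path)
  series <- purrr::map(file.path(dir, manifest$filename), read_series)
  tibble::tibble(
    series_id = sub("\\.[^.]*$", "", manifest$filename),
    class = manifest$class,
    n = lengths(series),
    series = series
  )
}
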