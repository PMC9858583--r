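Package: slpen
Title: Slope Entropy with Analytic and Heuristic Max-Min Normalisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Slope Entropy (SlpEn) of univariate time series from
    symbolised consecutive-sample differences, using the number of unique
    symbolic patterns found as the histogram normaliser. Provides analytic
    and heuristic lower and upper reference bounds so that SlpEn values can
    be rescaled into [0,1] by max-min normalisation without altering
    threshold-based classification, together with seeded synthetic signal
    generators, regression models for the pattern-count growth with the
    embedding dimension, and a single-feature classification harness for
    verifying normalisation invariance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
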