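test_that("the five symbol conditions partition the real line, boundaries included", {
  params <- slpen_params(m = 3, delta = 0.001, gamma = 0.8)
  # one and only one condition must hold for any finite difference
  set.seed(11)
  d <- c(runif(500, -3, 3),
         0.001, -0.001, 0.8, -0.8,                     # exact boundaries
         0.001 + 1e-15, 0.8 + 1e-15, 0, -2.5, 2.5)
  s <- slope_symbol(d, params)
  expect_true(all(s %in% -2:2))
  holds <- cbind(d > 0.8,
                 d <= 0.8 & d > 0.001,
                 abs(d) <= 0.001,
                 d < -0.001 & d >= -0.8,
                 d < -0.8)
  expect_true(all(rowSums(holds) == 1))
  # printed boundary conventions: d = gamma -> +1, d = +/-delta -> 0, d = -gamma -> -1
  expect_identical(slope_symbol(c(0.8, 0.001, -0.8, -0.001, 1.0), params),
                   c(1L, 0L, -1L, 0L, 2L))
  expect_error(slope_symbol(NaN, params), class = "slpen_invalid_input")
  expect_error(slope_symbol(Inf, params), class = "slpen_invalid_input")
})

test_that("parameter validation enforces m >= 3 and 0 <= delta < gamma", {
  expect_error(slpen_params(m = 2), class = "slpen_invalid_input")
  expect_error(slpen_params(delta = 0.9, gamma = 0.8), class = "slpen_invalid_input")
  expect_error(slpen_params(delta = -0.1), class = "slpen_invalid_input")
  expect_error(slpen_params(delta = 0.5, gamma = 0.5), class = "slpen_invalid_input")
  expect_silent(slpen_params(m = 3, delta = 0, gamma = 1e-6))
})

test_that("encoding worked examples: constant, outlier and alternating series", {
  p4 <- slpen_params(m = 4, delta = 1e-3, gamma = 0.2)

  h <- pattern_histogram(rep(1, 66), p4)
  expect_identical(attr(h, "k"), 1L)
  expect_identical(h$pattern, "0,0,0")
  expect_identical(h$count, 63L)

  x <- rep(1, 66); x[34] <- 2   # one interior outlier carves out m new patterns
  h <- pattern_histogram(x, p4)
  expect_identical(attr(h, "k"), 5L)
  expect_identical(sum(h$count), 63L)
  expect_identical(h$count[h$pattern == "0,0,0"], 59L)
  singles <- h[h$pattern != "0,0,0", ]
  expect_true(all(singles$count == 1L))
  expect_true(all(grepl("2", singles$pattern)))

  h <- pattern_histogram(c(0, 1, 0, 1, 0, 1), slpen_params(m = 3))
  expect_setequal(h$pattern, c("-2,2", "2,-2"))
  expect_identical(h$count, c(2L, 2L))
})

test_that("series shorter than m or non-finite input is rejected", {
  expect_error(pattern_histogram(1:5, slpen_params(m = 6)),
               class = "slpen_series_too_short")
  expect_error(slope_entropy(c(1, NA, 3), slpen_params(m = 3)),
               class = "slpen_invalid_input")
  expect_error(slope_entropy(c(1, Inf, 3, 4), slpen_params(m = 3)),
               class = "slpen_invalid_input")
})

test_that("slope entropy matches the worked examples end to end", {
  p4 <- slpen_params(m = 4, delta = 1e-3, gamma = 0.2)
  expect_equal(slope_entropy(rep(1, 66), p4)$value, -376.57, tolerance = 1e-4)
  x <- rep(1, 66); x[34] <- 2
  r <- slope_entropy(x, p4)
  expect_equal(r$value, -40.16, tolerance = 1e-3)
  expect_identical(r$k, 5L)
  # two equally-filled bins: p_i = 2/2 = 1, so every term vanishes
  expect_equal(slope_entropy(c(0, 1, 0, 1, 0, 1), slpen_params(m = 3))$value, 0)
})

test_that("fast histogram is bit-identical to the naive oracle on random series", {
  set.seed(42)
  cases <- expand.grid(m = c(3, 4, 6, 9), rep = 1:5)
  for (i in seq_len(nrow(cases))) {
    m <- cases$m[i]
    n <- sample(m:200, 1)
    x <- switch(sample(3, 1),
                rnorm(n), runif(n, -2, 2), round(rnorm(n), 1))
    delta <- sample(c(1e-3, 1e-2, 0.1), 1)
    gamma <- sample(c(0.2, 0.8, 1.5), 1)
    h <- pattern_histogram(x, slpen_params(m, delta, gamma))
    ref <- naive_histogram(x, m, delta, gamma)
    got <- stats::setNames(h$count, h$pattern)
    expect_identical(sort(names(got)), sort(names(ref)))
    expect_identical(got[sort(names(got))],
                     stats::setNames(ref, names(ref))[sort(names(ref))])
    expect_equal(slope_entropy(x, slpen_params(m, delta, gamma))$value,
                 naive_slpen(x, m, delta, gamma), tolerance = 1e-12)
  }
})

test_that("histogram counts conserve the subsequence total and k respects its cap", {
  set.seed(7)
  for (i in 1:20) {
    m <- sample(3:8, 1)
    n <- sample(m:300, 1)
    x <- rnorm(n)
    h <- pattern_histogram(x, slpen_params(m))
    expect_identical(sum(h$count), n - m + 1L)
    expect_lte(attr(h, "k"), min(n - m + 1, 5^(m - 1)))
    expect_true(all(h$count >= 1L))
  }
})

test_that("constant-gradient series attain the exact minimum for any thresholds", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(20:500, 1)
    m <- sample(3:7, 1)
    step <- runif(1, -5, 5)
    x <- cumsum(c(0, rep(step, n - 1)))
    delta <- runif(1, 0, 0.5)
    gamma <- delta + runif(1, 0.01, 2)
    r <- slope_entropy(x, slpen_params(m, delta, gamma))
    expect_identical(r$k, 1L)
    n_sub <- n - m + 1
    expect_equal(r$value, -n_sub * log2(n_sub), tolerance = 1e-12)
  }
})

test_that("SlpEn depends only on the multiset of pattern counts", {
  # same count multiset {2, 2}, different patterns owning the counts
  a <- slope_entropy(c(0, 1, 0, 1, 0, 1), slpen_params(m = 3))      # (-2,2),(2,-2)
  b <- slope_entropy(c(0, 0.5, 0, 0.5, 0, 0.5), slpen_params(m = 3)) # (-1,1),(1,-1)
  expect_false(setequal(a$histogram$pattern, b$histogram$pattern))
  expect_identical(sort(a$histogram$count), sort(b$histogram$count))
  expect_equal(a$value, b$value)
})

test_that("the near-constant closed-form model matches the pipeline and its k = 1 limit", {
  expect_equal(slpen_constant_model(4995, 1), -4995 * log2(4995))
  # singleton-disturbance model agrees with the full pipeline on the outlier series
  x <- rep(1, 66); x[34] <- 2
  r <- slope_entropy(x, slpen_params(m = 4, delta = 1e-3, gamma = 0.2))
  expect_equal(slpen_constant_model(63, 5), r$value, tolerance = 1e-12)
  expect_error(slpen_constant_model(10, 11), class = "slpen_invalid_input")
  expect_error(slpen_constant_model(10, 0), class = "slpen_invalid_input")
})

test_that("tidy and glance methods expose the histogram and the summary", {
  r <- slope_entropy(rnorm(100), slpen_params(m = 4))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("pattern", "count", "p"))
  expect_equal(sum(td$count), r$n_sub)
  expect_equal(td$p, td$count / r$k)
  g <- glance(r)
  expect_identical(nrow(g), 1L)
  expect_equal(g$slpen, r$value)
  expect_equal(g$m, 4L)
})
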