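test_that("analytic extremes evaluate to their closed forms", {
  expect_equal(slpen_analytic_min(5000), -5000 * log2(5000))
  expect_equal(slpen_analytic_min(2), -2)
  expect_error(slpen_analytic_min(1), class = "slpen_invalid_input")
  expect_equal(slpen_exact_min(4995), -61369.91, tolerance = 1e-6)
  expect_equal(slpen_kstar(5000), exp(1) * sqrt(5000))
  expect_equal(slpen_analytic_max(5000), 2 * sqrt(5000) / (exp(1) * log(2)))
  expect_equal(slpen_analytic_max(5000), 75.06, tolerance = 1e-4)
})

test_that("integer brute force of the uniform-histogram expression tracks e*sqrt(N)", {
  for (n in c(10, 50, 100, 1000, 5000, 20000, 1e5)) {
    expect_lte(abs(brute_force_kmax(n) - round(slpen_kstar(n))), 1)
  }
  # closed-form peak value: f(k*) = 2*sqrt(N)/e in natural-log units
  n <- 5000
  f_nat <- function(k) (n / k) * log(k^2 / n)
  expect_equal(f_nat(slpen_kstar(n)), 2 * sqrt(n) / exp(1), tolerance = 1e-12)
})

test_that("heuristic lower bound applies one pattern per 100 samples", {
  expect_equal(slpen_heuristic_min(5000, 6), slpen_constant_model(4995, 50))
  expect_equal(slpen_heuristic_min(5000, 6), -650.1, tolerance = 1e-3)
  expect_equal(slpen_heuristic_min(1022, 6), slpen_constant_model(1017, 10))
  expect_equal(slpen_heuristic_min(1022, 6), -668, tolerance = 1e-3)
  # samples_per_pattern >= N collapses to the exact k = 1 minimum
  expect_equal(slpen_heuristic_min(500, 6, samples_per_pattern = 500),
               slpen_exact_min(495))
  # strictly tighter than the exact minimum whenever k_h >= 2
  for (n in c(200, 1000, 5000)) {
    expect_gt(slpen_heuristic_min(n, 6), slpen_exact_min(n - 5))
  }
})

test_that("heuristic upper bound uses the regression k, capped at the theoretical count", {
  fit <- fit_k_model(family = "power")
  khat <- round(0.0998 * 6^4.9136)           # about 665
  expect_equal(slpen_heuristic_max(5000, 6, fit),
               (5000 / khat) * log2(khat^2 / 5000), tolerance = 1e-6)
  expect_equal(slpen_heuristic_max(5000, 6, fit), 48.6, tolerance = 1e-3)
  # at m = 3 the power fit predicts ~22 > 2: value below the analytic max
  expect_lte(slpen_heuristic_max(5000, 3, fit), slpen_analytic_max(5000))
  # cap at 5^(m-1): power fit at m = 4 predicts ~91, below 125, but a steep
  # synthetic fit exceeds the theoretical count and must be clamped
  steep <- fit_k_model(tibble::tibble(m = 3:9, k_max = round(4^(3:9))),
                       family = "power")
  expect_gt(predict_k(steep, 6), 5^5)
  b <- slpen_bounds(5000, m = 6, scheme = "heuristic", fit = steep)
  expect_identical(b$k_upper, as.integer(5^5))
})

test_that("bounds objects are well formed across schemes", {
  ba <- slpen_bounds(5000, scheme = "analytic")
  expect_identical(ba$k_lower, 1L)
  expect_equal(ba$lower, -5000 * log2(5000))
  br <- recommended_bounds(5000, 6)
  expect_identical(br$scheme, "recommended")
  expect_equal(br$lower, -650.1, tolerance = 1e-3)
  expect_equal(br$upper, 75.06, tolerance = 1e-4)
  expect_lt(br$lower, 0)
  expect_gt(br$upper, 0)
  # lower < 0 < upper holds across a length sweep
  for (n in c(200, 1000, 10^4, 10^6)) {
    b <- recommended_bounds(n, 6)
    expect_true(b$lower < 0 && b$upper > 0)
  }
  expect_error(slpen_bounds(5000, scheme = "heuristic"),
               class = "slpen_invalid_configuration")
})

test_that("normalisation maps endpoints, clips at zero and is monotone above the clip", {
  b <- slpen_bounds(5000, scheme = "analytic")
  v <- normalise_slpen(c(b$lower, b$upper), b)
  expect_equal(v$normalised, c(0, 1))
  expect_false(any(v$clipped))

  br <- recommended_bounds(5000)
  v <- normalise_slpen(c(-70000, br$lower - 1, br$lower, 0, 50), br)
  expect_true(all(v$normalised >= 0 & v$normalised <= 1))
  expect_identical(v$clipped, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(v$normalised[3], 0)
  # strictly increasing above the lower bound
  raws <- sort(runif(50, br$lower, br$upper))
  z <- normalise_slpen(raws, br)$normalised
  expect_true(all(diff(z) > 0))
})

test_that("raw SlpEn of random series never violates the analytic bounds", {
  set.seed(99)
  for (i in 1:40) {
    m <- sample(3:8, 1)
    n <- sample(50:400, 1)
    x <- switch(sample(3, 1), rnorm(n), runif(n, -3, 3),
                cumsum(rnorm(n)))
    delta <- sample(c(1e-3, 1e-2), 1)
    gamma <- sample(c(0.2, 0.8), 1)
    r <- slope_entropy(x, slpen_params(m, delta, gamma))
    expect_gte(r$value, slpen_exact_min(r$n_sub))
    expect_lte(r$value, slpen_analytic_max(n))
  }
})
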