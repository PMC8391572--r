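test_that("logistic evaluation and reparameterization agree", {
  p <- logistic_params(L = 10, k = 0.07, x0 = 20)
  expect_equal(logistic(p$x0, p), 5, tolerance = 1e-12)
  expect_lt(abs(logistic(1e6, p) - 10), 1e-9)     # saturates at the maximum
  # reciprocal form at converted (a, b) equals the (L, k, x0) form
  q <- logistic_params(L = 10, a = p$a, b = p$b)
  x <- seq(-10, 80, 0.5)
  expect_equal(logistic(x, q), 10 / (1 + exp(-0.07 * (x - 20))),
               tolerance = 1e-12)
  expect_error(logistic_params(L = -1, a = 1, b = 0.9), "positive")
  expect_error(logistic_params(L = 10, a = 1, b = 1.2), "\\(0, 1\\)")
})

test_that("short-term annoyance follows the reconstructed jury model", {
  expect_equal(short_term_annoyance(0), 1 / 0.563, tolerance = 1e-12)
  expect_equal(short_term_annoyance(1e5), 10, tolerance = 1e-9)
  grid <- seq(0, 60, 1)
  expect_true(all(diff(short_term_annoyance(grid)) > 0))
  expect_true(all(short_term_annoyance(grid) <= 10))
  expect_error(short_term_annoyance(-1), "non-negative")
})

test_that("long-term %HA follows the reconstructed survey model", {
  expect_equal(long_term_pct_ha(0), 1 / 0.053, tolerance = 1e-12)  # about 18.9
  expect_equal(long_term_pct_ha(20), 30.0, tolerance = 0.1)
  expect_equal(long_term_pct_ha(1e5), 100, tolerance = 1e-9)
  expect_gt(long_term_pct_ha(0), 0)   # nonzero %HA even at zero loudness
  grid <- seq(0, 60, 1)
  expect_true(all(diff(long_term_pct_ha(grid)) > 0))
})

test_that("noiseless logistic fits recover the generating parameters", {
  x <- seq(0, 60, 2)
  truth <- logistic_params(L = 10, a = 0.463, b = 0.936)
  f <- fit_logistic(x, logistic(x, truth), 10)
  expect_equal(f$params$b, truth$b, tolerance = 1e-6)
  expect_equal(f$params$a, truth$a, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_logistic(x, rep(5, length(x)), 10), "degenerate")
  expect_error(fit_logistic(c(0, 1, 2), c(1, 2, 3), 10), "4 distinct")
})

test_that("fitted base is recovered across the survey-like parameter range", {
  # replicated noisy refits recover b to within 0.01 in the median
  for (b_true in c(0.92, 0.97)) {
    truth <- logistic_params(L = 100, a = 0.043, b = b_true)
    x <- seq(0, 45, 2.5)
    rec <- vapply(1:25, function(s) {
      set.seed(s)
      y <- pmin(pmax(logistic(x, truth) + stats::rnorm(length(x), 0, 0.5),
                     1e-3), 99.9)
      fit_logistic(x, y, 100)$params$b
    }, numeric(1))
    expect_lt(abs(stats::median(rec) - b_true), 0.01)
  }
})

test_that("%HA counts ratings at or above the cutoff", {
  expect_equal(pct_highly_annoyed(c(8, 9, 10, 0)), 75)
  expect_equal(pct_highly_annoyed(rep(7, 20)), 0)
  expect_error(pct_highly_annoyed(integer(0)), "no ratings")
  expect_error(pct_highly_annoyed(c(3, 11)), "0..10")
  set.seed(42)
  r <- stats::rbinom(10000, 1, 0.3) * 10     # 30 % rate a 10, rest 0
  expect_lt(abs(pct_highly_annoyed(r) - 30), 1)
})

test_that("loudness binning covers the data in half-open 5-sone bins", {
  set.seed(7)
  loud <- stats::runif(500, 0, 44.9)
  bins <- bin_by_loudness(loud, loud > 20)
  expect_equal(nrow(bins), 9)
  expect_equal(bins$lower, seq(0, 40, 5))
  expect_true(all(bins$upper - bins$lower == 5))
  one <- bin_by_loudness(12, TRUE)
  expect_equal(one$n, c(0, 0, 1))
  expect_equal(one$lower[one$n == 1], 10)
  expect_error(bin_by_loudness(-1, TRUE), "non-negative")
})

test_that("indoor corrections are source-specific", {
  expect_equal(indoor_level(70, "aircraft"), 55)
  expect_equal(indoor_level(70, "road"), 54.2)
  expect_equal(indoor_level(0, "aircraft"), -15)   # no flooring
  expect_error(indoor_level(70, "rail"))
})

test_that("fitted models serialize and read back", {
  x <- seq(0, 45, 5)
  f <- fit_logistic(x, long_term_pct_ha(x), 100, kind = "long_term")
  p <- tempfile(fileext = ".json")
  model_to_file(f, p)
  g <- model_from_file(p)
  expect_equal(g$params$b, f$params$b, tolerance = 1e-9)
  expect_equal(g$kind, "long_term")
  expect_equal(g$ha_cutoff, 8)
})
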