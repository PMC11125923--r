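test_that("pearson matches hand-computed and degenerate cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(x, rep(2, 4)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("correlation screening keeps signal indices and drops noise", {
  truth <- cc_plsr_model(c(NDVI = 32.84, OSAVI = 26.39, EVI = 31.824), 16.563)
  d <- make_vi_cc_dataset(150, truth, noise_sd = 1, seed = 6, mix = 0.8,
                          include_all_vis = TRUE)
  all_in <- screen_vis(d, threshold = 0)
  expect_setequal(all_in$vi, vi_names())
  expect_true(all(diff(all_in$abs_r) <= 0))
  sel <- screen_vis(d, threshold = 0.8)
  expect_setequal(sel$vi, c("NDVI", "OSAVI", "EVI"))
  expect_warning(none <- screen_vis(d, threshold = 1 + 1e-9), "no index")
  expect_equal(nrow(none), 0)
  expect_error(screen_vis(dplyr::select(d, -"cc")), "response column")
})

test_that("every regression family recovers its own noiseless data exactly", {
  x <- seq(0.1, 0.95, length.out = 30)
  cases <- list(
    linear      = function(x) 31.06 + 70.78 * x,
    logarithmic = function(x) 90.13 + 39.55 * log(x),
    exponential = function(x) 12 * exp(1.8 * x),
    power       = function(x) 95 * x^0.7
  )
  truth <- list(linear = c(31.06, 70.78), logarithmic = c(90.13, 39.55),
                exponential = c(12, 1.8), power = c(95, 0.7))
  for (fam in names(cases)) {
    d <- tibble::tibble(OSAVI = x, cc = cases[[fam]](x))
    f <- fit_cc_regression(d, "OSAVI", fam)
    expect_equal(unname(c(f$a, f$b)), truth[[fam]], tolerance = 1e-9,
                 info = fam)
  }
})

test_that("linear fits equal the closed-form least-squares oracle", {
  set.seed(13)
  for (i in 1:5) {
    x <- runif(25); y <- 40 + 30 * x + rnorm(25, sd = 4)
    f <- fit_cc_regression(tibble::tibble(v = x, cc = y), "v", "linear")
    # normal equations computed directly
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    expect_equal(f$b, b, tolerance = 1e-10)
    expect_equal(f$a, a, tolerance = 1e-10)
  }
})

test_that("domain constraints are enforced at fit and predict time", {
  d <- tibble::tibble(v = c(-0.1, 0.5, 0.8), cc = c(10, 50, 80))
  expect_error(fit_cc_regression(d, "v", "logarithmic"), "positive predictor")
  expect_error(fit_cc_regression(d, "v", "power"), "positive predictor")
  d2 <- tibble::tibble(v = c(0.2, 0.5, 0.8), cc = c(-5, 50, 80))
  expect_error(fit_cc_regression(d2, "v", "exponential"), "positive response")
  m <- cc_regression_model("logarithmic", 90.13, 39.55, "OSAVI")
  expect_error(predict(m, c(0.5, 0)), "non-positive")
})

test_that("published-style inversion equations evaluate as written", {
  osavi <- cc_regression_model("logarithmic", 90.13, 39.55, "OSAVI")
  expect_equal(predict(osavi, 1), 90.13)
  evi <- cc_regression_model("linear", 31.06, 70.78, "EVI")
  expect_equal(predict(evi, 1) - predict(evi, 0), 70.78)
  plsr <- cc_plsr_model(c(NDVI = 32.84, OSAVI = 26.39, EVI = 31.824), 16.563)
  expect_equal(predict(plsr, tibble::tibble(NDVI = 0, OSAVI = 0, EVI = 0)),
               16.563)
  # clipping is optional and off by default
  expect_gt(predict(evi, 1.2), 100)
  expect_equal(predict(evi, 1.2, clip = TRUE), 100)
})

test_that("evaluation reports the error and agreement statistics", {
  ev <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$rmse, 0)
  expect_equal(ev$r2, 1)
  ev2 <- evaluate(c(0, 0), c(0, 10))
  expect_equal(ev2$rmse, sqrt(100 / 2))
  obs <- c(2, 4, 6, 8)
  ev3 <- evaluate(rep(mean(obs), 4), obs)
  expect_equal(ev3$r2, 0)
  expect_warning(ev4 <- evaluate(c(1, 2, 3), rep(5, 3)), "zero variance")
  expect_true(is.na(ev4$r2))
  # rmse = 0 iff elementwise equality
  set.seed(4)
  a <- runif(10); b <- a; b[3] <- b[3] + 1e-6
  expect_gt(evaluate(b, a)$rmse, 0)
  # the literal variance-ratio statistic is reported alongside
  ev5 <- evaluate(c(1, 2, 4), c(1, 2, 3))
  expect_equal(ev5$r2_ratio,
               sum((c(1, 2, 3) - 2)^2) / sum((c(1, 2, 4) - 2)^2))
})
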