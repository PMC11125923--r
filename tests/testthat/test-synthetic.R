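test_that("scene generation is deterministic and hits the coverage target", {
  sp <- scene_spec(width = 64, height = 64, row_period = 16, row_width = 8,
                   target_coverage = 0.5, seed = 7)
  a <- make_scene(sp)
  b <- make_scene(sp)
  expect_identical(a$stack$bands, b$stack$bands)
  expect_identical(a$canopy_mask, b$canopy_mask)
  expect_equal(a$true_coverage, 50) # 32 of 64 columns, exact
  expect_equal(a$true_coverage,
               100 * sum(a$canopy_mask) / length(a$canopy_mask))
})

test_that("degenerate coverage targets give all-soil and all-canopy scenes", {
  empty <- make_scene(scene_spec(target_coverage = 0, seed = 1))
  expect_equal(empty$true_coverage, 0)
  expect_false(any(empty$canopy_mask))
  full <- make_scene(scene_spec(target_coverage = 1, row_period = 16,
                                row_width = 16, seed = 1))
  expect_equal(full$true_coverage, 100)
  expect_true(all(full$canopy_mask))
})

test_that("infeasible stripe geometry is an explicit error", {
  expect_error(make_scene(scene_spec(row_period = 16, row_width = 8,
                                     target_coverage = 0.9)),
               "infeasible")
  expect_error(scene_spec(row_period = 8, row_width = 10), "row_width")
  expect_error(scene_spec(target_coverage = 1.2), "target_coverage")
})

test_that("scenes have the spectral contrast that makes Otsu meaningful", {
  for (seed in 1:4) {
    tb <- tiny_scene(coverage = 0.4, noise_sd = 0.03, seed = seed)
    red <- tb$stack$bands$red; nir <- tb$stack$bands$nir
    expect_lt(mean(red[tb$canopy_mask]), mean(red[!tb$canopy_mask]))
    expect_gt(mean(nir[tb$canopy_mask]), mean(nir[!tb$canopy_mask]))
  }
})

test_that("spectra must satisfy the canopy/soil contrast invariants", {
  bad_red <- veg_spectrum_default(); bad_red[["red"]] <- 0.5
  expect_error(scene_spec(veg_spectrum = bad_red), "darker than soil")
  bad_nir <- veg_spectrum_default(); bad_nir[["nir"]] <- 0.1
  expect_error(scene_spec(veg_spectrum = bad_nir), "brighter than soil")
})

test_that("weather series respects physical invariants and seasonality", {
  w <- make_weather(365, seed = 11)
  expect_equal(nrow(w), 365)
  expect_true(all(w$tmin <= w$tmax))
  expect_true(all(w$precipitation >= 0))
  expect_true(all(w$et0 > 0))
  summer <- w$doy >= 172 & w$doy <= 264
  winter <- w$doy <= 59 | w$doy >= 335
  tmean <- (w$tmin + w$tmax) / 2
  expect_gt(mean(tmean[summer]), mean(tmean[winter]))
  expect_identical(w, make_weather(365, seed = 11))
})

test_that("single-day and zero-noise flat climates behave as exact limits", {
  one <- make_weather(1, seed = 2)
  expect_equal(nrow(one), 1)
  flat <- make_weather(10, climate = list(t_amp = 0, t_noise_sd = 0,
                                          precip_prob = 0,
                                          precip_prob_amp = 0,
                                          et0_amp = 0, et0_noise_sd = 0),
                       seed = 5)
  expect_equal(length(unique(flat$tmin)), 1)
  expect_equal(length(unique(flat$et0)), 1)
  expect_true(all(flat$precipitation == 0))
})

test_that("noiseless VI-CC tables are exact functions of the truth model", {
  truth <- cc_regression_model("linear", 31.06, 70.78, "EVI")
  d <- make_vi_cc_dataset(40, truth, noise_sd = 0, seed = 3)
  f <- fit_cc_regression(d, "EVI", "linear")
  expect_equal(f$a, 31.06, tolerance = 1e-9)
  expect_equal(f$b, 70.78, tolerance = 1e-9)
  expect_equal(nrow(make_vi_cc_dataset(3, truth, seed = 1)), 3)
})

test_that("noisy log-truth tables let the same family recover coefficients", {
  # tolerance frozen from a 20-seed Monte-Carlo of the fitting oracle:
  # max |a - 90.13| = 0.96, max |b - 39.55| = 1.24 at n = 200, sd = 3
  truth <- cc_regression_model("logarithmic", 90.13, 39.55, "OSAVI")
  for (seed in c(2, 9, 17)) {
    d <- make_vi_cc_dataset(200, truth, noise_sd = 3, seed = seed)
    f <- fit_cc_regression(d, "OSAVI", "logarithmic")
    expect_lt(abs(f$a - 90.13), 3)
    expect_lt(abs(f$b - 39.55), 3)
  }
})

test_that("observed-coverage trajectories are exact at zero noise and seeded", {
  w <- quick_weather(180)
  p <- crop_params()
  days <- c(20L, 60L, 120L, 170L)
  obs0 <- make_observations(p, w, days, noise_sd = 0, seed = 1)
  sim <- run_crop_model(p, w)
  expect_equal(obs0$cc, sim$daily$cc[days])
  expect_equal(cc_cost(sim$daily$cc[days], obs0$cc), 0)
  obs1 <- make_observations(p, w, days, noise_sd = 2, seed = 4)
  expect_identical(obs1, make_observations(p, w, days, noise_sd = 2, seed = 4))
  expect_true(all(obs1$cc >= 0 & obs1$cc <= p$mcc))
  expect_error(make_observations(p, w, c(5L, 500L)), "horizon")
})
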