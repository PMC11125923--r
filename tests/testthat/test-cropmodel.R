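test_that("thermal time follows the capped degree-day rule", {
  w <- tibble::tibble(tmin = c(7, 16, 31), tmax = c(7, 24, 39))
  tt <- thermal_time(w, tbase = 7, tupper = 30)
  expect_equal(tt$gdd, c(0, 13, 23)) # at base; 20-7; capped at 30-7
  expect_true(all(diff(tt$gdd_cum) >= 0))
  w2 <- make_weather(200, seed = 5)
  tt2 <- thermal_time(w2, 7, 30)
  expect_true(all(tt2$gdd >= 0 & tt2$gdd <= 23))
})

test_that("canopy development is bounded, monotone, and frozen at cgc = 0", {
  p <- crop_params()
  gdd <- rep(10, 200)
  cc <- simulate_canopy(p, gdd, cgc = 0.003)
  expect_true(all(cc >= 0 & cc <= p$mcc))
  expect_true(all(diff(cc) >= 0))
  expect_gt(cc[200], p$mcc - 0.5) # approaches the maximum
  expect_equal(simulate_canopy(p, gdd, cgc = 0),
               rep(p$cc_ini * p$den / 5000, 200))
})

test_that("canopy development grows through both phases continuously", {
  # a sparse initial canopy passes through the exponential phase
  p <- crop_params(cc_ini = 5, mcc = 70)
  cc <- simulate_canopy(p, rep(10, 400), cgc = 0.003)
  expect_equal(cc[1], 5 * exp(0.003 * 10), tolerance = 1e-12)
  expect_true(all(diff(cc) >= -1e-12))
  expect_gt(cc[400], 69) # reaches the asymptote from a sparse start
  # an established canopy starts exactly at its initial coverage
  p2 <- crop_params(cc_ini = 60, mcc = 70)
  cc2 <- simulate_canopy(p2, c(0, rep(10, 99)), cgc = 0.003)
  expect_equal(cc2[1], 60)
})

test_that("raising initial coverage never lowers the trajectory", {
  gdd <- rep(8, 150)
  lo <- simulate_canopy(crop_params(cc_ini = 57), gdd)
  hi <- simulate_canopy(crop_params(cc_ini = 63), gdd)
  expect_true(all(hi >= lo))
})

test_that("cold days and water stress gate canopy expansion", {
  p <- crop_params(tmg = 7)
  gdd <- rep(10, 50)
  warm <- simulate_canopy(p, gdd, tmean = rep(20, 50))
  cold <- simulate_canopy(p, gdd, tmean = c(rep(4, 25), rep(20, 25)))
  expect_true(all(cold <= warm))
  expect_equal(cold[1:25], rep(p$cc_ini, 25)) # frozen below tmg
  stressed <- simulate_canopy(p, gdd, ks = 0.5)
  expect_true(all(stressed <= warm))
})

test_that("transpiration and biomass follow the crop-coefficient arithmetic", {
  expect_equal(transpiration(0, 0.8, 5), 0)
  expect_equal(transpiration(100, 0.8, 5), 4)
  expect_equal(transpiration(50, 0.8, 5), 2)
  expect_equal(transpiration(50, 0.8, 5, ks = 0.5), 1)
  by <- biomass_yield(tr = rep(2.5, 4), et0 = rep(1, 4), wp = 12, hi = 5)
  expect_equal(by$biomass, 120) # wp * sum(Tr/ET0) = 12 * 10
  expect_equal(by$yield, 6)
  z <- biomass_yield(rep(0, 5), rep(3, 5), 12, 5)
  expect_equal(z$biomass, 0)
  expect_equal(z$yield, 0)
  expect_equal(yield_response(1.25, 100, 100), 1) # no deficit, no loss
  expect_equal(yield_response(1.25, 100, 80), 1 - 1.25 * 0.2)
})

test_that("a dry, demand-free day leaves the soil untouched", {
  so <- soil_profile()
  st <- soil_water_step(so, precipitation = 0, et0 = 0, cc = 50, kcb = 0.8)
  expect_equal(st$soil$theta, so$theta)
  expect_true(all(abs(st$fluxes[c("runoff", "percolation", "es", "tr")]) == 0))
})

test_that("rain filling the top-layer deficit is stored without percolation", {
  so <- soil_profile(theta = 0.25, theta_fc = 0.30)
  deficit_top <- (0.30 - 0.25) * 0.25 * 1000 # 12.5 mm
  st <- soil_water_step(so, precipitation = deficit_top, et0 = 0, cc = 0,
                        kcb = 0.8)
  expect_equal(st$soil$theta[1], 0.30)
  expect_equal(st$soil$theta[-1], so$theta[-1])
  expect_equal(st$fluxes$percolation, 0)
  expect_equal(st$fluxes$delta_storage, deficit_top)
})

test_that("extraction demands are scaled, never drawing below wilting point", {
  so <- soil_profile(n_layers = 2, theta = 0.125, theta_wp = 0.12)
  avail <- sum((0.125 - 0.12) * 0.25 * 1000 * c(1, 1)) # 2.5 mm
  st <- soil_water_step(so, precipitation = 0, et0 = 10, cc = 100, kcb = 0.8)
  expect_lte(st$fluxes$tr + st$fluxes$es, avail + 1e-12)
  expect_true(all(st$soil$theta >= 0.12 - 1e-12))
})

test_that("the daily water budget closes over a full year", {
  w <- make_weather(365, seed = 6)
  for (seed in c(1, 2)) {
    p <- draw_params(seed)
    sim <- run_crop_model(p, w, soil = soil_profile(),
                          config = list(water_limited = seed == 2))
    expect_lt(max(abs(closure_residuals(sim))), 1e-9)
  }
})

test_that("full runs are deterministic and respect coverage bounds", {
  w <- quick_weather(150)
  p <- draw_params(5)
  a <- run_crop_model(p, w, soil = soil_profile())
  b <- run_crop_model(p, w, soil = soil_profile())
  expect_identical(a, b)
  expect_true(all(a$daily$cc >= 0 & a$daily$cc <= p$mcc))
  one <- run_crop_model(crop_params(), w[1, ])
  expect_equal(one$daily$cc, crop_params()$cc_ini)
})

test_that("warmer weather below the cap never slows canopy development", {
  w <- quick_weather(150)
  p <- crop_params()
  warm <- w
  warm$tmin <- pmin(w$tmin + 3, p$tupper)
  warm$tmax <- pmin(w$tmax + 3, p$tupper)
  cc_base <- run_crop_model(p, w)$daily$cc
  cc_warm <- run_crop_model(p, warm)$daily$cc
  expect_true(all(cc_warm >= cc_base - 1e-12))
})

test_that("wetter seasons never yield less under water limitation", {
  w <- make_weather(365, climate = list(precip_prob = 0.08, precip_mean = 5),
                    seed = 9)
  wet <- w
  wet$precipitation <- wet$precipitation * 2
  p <- crop_params()
  cfg <- list(water_limited = TRUE)
  dry_run <- run_crop_model(p, w, soil = soil_profile(theta = 0.16),
                            config = cfg)
  wet_run <- run_crop_model(p, wet, soil = soil_profile(theta = 0.16),
                            config = cfg)
  expect_gte(wet_run$yield, dry_run$yield)
})
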