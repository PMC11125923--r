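#' Crop parameter set
#'
#' The nine crop parameters adjusted by the assimilation: initial and
#' maximum canopy coverage, plant density, water productivity, harvest
#' index, basal transpiration coefficient, and the three temperature
#' thresholds controlling thermal time and canopy expansion.
#'
#' @param cc_ini initial canopy coverage, % (0 < cc_ini <= mcc).
#' @param den plant density, plants per hectare. Scales the effective
#'   initial coverage multiplicatively around the reference density 5000.
#' @param mcc maximum canopy coverage (CCx), %.
#' @param wp water productivity: biomass per unit normalized transpiration
#'   (sum of daily Tr/ET0), consistent internal units.
#' @param hi harvest index, % of biomass realized as yield.
#' @param kcb basal crop transpiration coefficient, unitless.
#' @param tmg minimum growth temperature, deg C: canopy expansion halts on
#'   days whose mean temperature falls below it.
#' @param tupper upper temperature threshold for thermal time, deg C.
#' @param tbase base temperature for thermal time, deg C.
#' @return a `crop_params` object (named list).
#' @export
crop_params <- function(cc_ini = 60, den = 5000, mcc = 70, wp = 12, hi = 5,
                        kcb = 0.8, tmg = 7, tupper = 30, tbase = 7) {
  p <- list(cc_ini = cc_ini, den = den, mcc = mcc, wp = wp, hi = hi,
            kcb = kcb, tmg = tmg, tupper = tupper, tbase = tbase)
  if (any(!vapply(p, is.numeric, logical(1)))) abort("all parameters must be numeric.")
  if (!(cc_ini > 0 && cc_ini <= mcc && mcc <= 100)) {
    abort("need 0 < cc_ini <= mcc <= 100.")
  }
  if (!(tbase < tupper)) abort("need tbase < tupper.")
  if (den <= 0 || wp < 0 || hi < 0 || kcb < 0) {
    abort("den must be positive; wp, hi, kcb non-negative.")
  }
  structure(p, class = "crop_params")
}

#' @export
print.crop_params <- function(x, ...) {
  cat("<crop_params>\n")
  print(unlist(x))
  invisible(x)
}

#' Reference bounds for the assimilated crop parameters
#'
#' Initial value and allowed range for each of the nine parameters, the
#' box the particle swarm searches.
#'
#' @return tibble with columns `param`, `init`, `lower`, `upper`.
#' @export
default_param_bounds <- function() {
  tibble::tribble(
    ~param,    ~init, ~lower, ~upper,
    "cc_ini",     60,     57,     63,
    "den",      5000,   4750,   5250,
    "mcc",        70,     66,     74,
    "wp",         12,   11.4,   12.6,
    "hi",          5,   4.75,   5.25,
    "kcb",       0.8,   0.76,   0.84,
    "tmg",         7,   6.65,   7.35,
    "tupper",     30,   28.5,   31.5,
    "tbase",       7,   6.65,   7.35
  )
}

#' Layered soil profile
#'
#' @param n_layers number of layers.
#' @param thickness layer thickness, m.
#' @param theta initial volumetric water content, m3/m3 (recycled).
#' @param theta_fc,theta_wp,theta_sat field capacity, wilting point and
#'   saturation, m3/m3 (recycled across layers).
#' @return a `soil_profile` tibble, one row per layer.
#' @export
soil_profile <- function(n_layers = 4, thickness = 0.25, theta = 0.25,
                         theta_fc = 0.30, theta_wp = 0.12, theta_sat = 0.45) {
  out <- tibble::tibble(
    layer = seq_len(n_layers),
    thickness = rep_len(thickness, n_layers),
    theta = rep_len(theta, n_layers),
    theta_fc = rep_len(theta_fc, n_layers),
    theta_wp = rep_len(theta_wp, n_layers),
    theta_sat = rep_len(theta_sat, n_layers)
  )
  if (any(!(out$theta_wp < out$theta_fc & out$theta_fc < out$theta_sat))) {
    abort("need theta_wp < theta_fc < theta_sat in every layer.")
  }
  if (any(out$theta < 0 | out$theta > out$theta_sat)) {
    abort("initial theta must lie in [0, theta_sat].")
  }
  class(out) <- c("soil_profile", class(out))
  out
}

#' Daily thermal time (growing degree days)
#'
#' `GDD = max(0, min(Tmean, tupper) - tbase)` with `Tmean = (Tmin + Tmax)/2`.
#'
#' @param weather tibble with columns `tmin`, `tmax` (deg C).
#' @param tbase,tupper base and upper temperature thresholds, deg C.
#' @return tibble with `day`, `tmean`, `gdd`, `gdd_cum` (non-decreasing).
#' @export
thermal_time <- function(weather, tbase, tupper) {
  stopifnot(all(c("tmin", "tmax") %in% names(weather)), tbase < tupper)
  tmean <- (weather$tmin + weather$tmax) / 2
  gdd <- pmax(0, pmin(tmean, tupper) - tbase)
  tibble::tibble(day = seq_along(gdd), tmean = tmean, gdd = gdd,
                 gdd_cum = cumsum(gdd))
}

# Closed-form canopy-cover development in gated thermal time.
# Exponential growth from cc0 while CC < mcc/2, then exponential decay of
# the remaining gap toward mcc; the two branches join continuously at
# t* = ln(mcc / (2 cc0)) / cgc. For cc0 >= mcc/2 (an established perennial
# canopy) development starts directly in the decay branch so CC(0) = cc0.
canopy_curve <- function(t_gdd, cc0, mcc, cgc) {
  cc0 <- min(max(cc0, 1e-9), mcc)
  if (cgc <= 0) return(rep(cc0, length(t_gdd)))
  if (cc0 < mcc / 2) {
    t_star <- log(mcc / (2 * cc0)) / cgc
    cc_half <- mcc / 2
  } else {
    t_star <- 0
    cc_half <- cc0
  }
  cc <- ifelse(t_gdd < t_star,
               cc0 * exp(cgc * t_gdd),
               mcc - (mcc - cc_half) * exp(-cgc * (t_gdd - t_star)))
  pmin(pmax(cc, 0), mcc)
}

#' Simulate canopy-cover development
#'
#' Thermal-time driven logistic-style development: exponential expansion
#' from the effective initial coverage while CC is below half the maximum,
#' then exponential approach to the maximum `mcc`. Expansion is suppressed
#' (the thermal clock does not advance) on days where the mean temperature
#' falls below `tmg` or where the water-stress coefficient `ks < 1`
#' (multiplicative gating). Plant density scales the effective initial
#' coverage as `cc_ini * den / 5000`.
#'
#' @param params [crop_params()].
#' @param gdd daily growing-degree-day vector (see [thermal_time()]).
#' @param tmean daily mean temperature, same length as `gdd`.
#' @param ks daily water-stress coefficient in \[0, 1\] (1 = no stress);
#'   scalar or vector.
#' @param cgc canopy growth coefficient per unit GDD (configuration
#'   constant, not an assimilated parameter).
#' @return numeric vector of daily canopy coverage, % in \[0, mcc\].
#' @export
simulate_canopy <- function(params, gdd, tmean = NULL, ks = 1, cgc = 0.003) {
  stopifnot(inherits(params, "crop_params"))
  n <- length(gdd)
  ks <- rep_len(ks, n)
  gate <- ks
  if (!is.null(tmean)) gate <- gate * as.numeric(tmean >= params$tmg)
  clock <- cumsum(gdd * gate)
  cc0 <- params$cc_ini * params$den / 5000
  canopy_curve(clock, cc0, params$mcc, cgc)
}

#' Daily crop transpiration
#'
#' Crop-coefficient partition of reference evapotranspiration:
#' `Tr = ks * kcb * (CC/100) * ET0`.
#'
#' @param cc canopy coverage, %.
#' @param kcb basal transpiration coefficient.
#' @param et0 reference evapotranspiration, mm.
#' @param ks water-stress coefficient in \[0, 1\].
#' @return transpiration, mm.
#' @export
transpiration <- function(cc, kcb, et0, ks = 1) {
  stopifnot(all(cc >= 0 & cc <= 100))
  ks * kcb * (cc / 100) * et0
}

#' Water-driven biomass and yield
#'
#' Biomass accumulates as water productivity times normalized
#' transpiration, `B = wp * sum(Tr/ET0)` over days with `ET0 > 0`; yield is
#' the harvest-index share, `Y = (hi/100) * B`.
#'
#' @param tr daily transpiration, mm.
#' @param et0 daily reference evapotranspiration, mm.
#' @param wp water productivity.
#' @param hi harvest index, %.
#' @return list with `biomass` and `yield` (consistent internal units).
#' @export
biomass_yield <- function(tr, et0, wp, hi) {
  stopifnot(length(tr) == length(et0))
  ok <- et0 > 0
  b <- wp * sum(tr[ok] / et0[ok])
  list(biomass = b, yield = (hi / 100) * b)
}

#' Relative yield under evapotranspiration deficit
#'
#' The classical linear yield-response-to-water relation: relative yield
#' `1 - ky * (et_potential - et_actual) / et_potential`. Equal actual and
#' potential evapotranspiration gives relative yield 1 (no deficit).
#'
#' @param ky yield-response factor.
#' @param et_potential potential crop evapotranspiration, mm.
#' @param et_actual actual crop evapotranspiration, mm.
#' @return relative yield (unitless).
#' @export
yield_response <- function(ky, et_potential, et_actual) {
  stopifnot(et_potential > 0)
  1 - ky * (et_potential - et_actual) / et_potential
}

# tipping-bucket day update on raw vectors (fast path used inside run())
# theta etc. are per-layer vectors; water amounts in mm.
soil_step_raw <- function(theta, thick, fc, wp, sat, precip, es_dem, tr_dem,
                          infil_max = 50) {
  mm <- thick * 1000 # mm of water per unit theta
  storage0 <- sum(theta * mm)
  runoff <- max(0, precip - infil_max)
  inflow <- precip - runoff
  # infiltration fills layers to field capacity top-down
  for (j in seq_along(theta)) {
    if (inflow <= 0) break
    room <- max(0, (fc[j] - theta[j]) * mm[j])
    add <- min(inflow, room)
    theta[j] <- theta[j] + add / mm[j]
    inflow <- inflow - add
  }
  percolation <- inflow # excess beyond field capacity drains from the bottom
  # soil evaporation from the top layer, floored at wilting point
  avail_top <- max(0, (theta[1] - wp[1]) * mm[1])
  es <- min(es_dem, avail_top)
  theta[1] <- theta[1] - es / mm[1]
  # transpiration over rooted layers proportional to available water
  avail <- pmax(0, (theta - wp) * mm)
  tr <- min(tr_dem, sum(avail))
  if (tr > 0 && sum(avail) > 0) {
    take <- tr * avail / sum(avail)
    theta <- theta - take / mm
  }
  storage1 <- sum(theta * mm)
  list(theta = theta,
       fluxes = c(precipitation = precip, runoff = runoff,
                  infiltration = precip - runoff - percolation,
                  percolation = percolation, es = es, tr = tr,
                  delta_storage = storage1 - storage0))
}

#' One daily step of the layered soil-water balance
#'
#' Tipping-bucket update: infiltration (capped at `infil_max` mm/day,
#' surface excess becomes runoff) fills layers to field capacity top-down;
#' the remainder leaves the bottom layer as deep percolation; soil
#' evaporation `(1 - CC/100) * ke * ET0` is taken from the top layer and
#' crop transpiration from all layers proportionally to available water.
#' Extraction never draws a layer below wilting point: demands exceeding
#' available water are scaled down. The daily budget closes exactly:
#' `delta_storage = precipitation - runoff - percolation - es - tr`.
#'
#' @param soil a [soil_profile()].
#' @param precipitation daily precipitation, mm.
#' @param et0 reference evapotranspiration, mm.
#' @param cc canopy coverage, %.
#' @param kcb basal transpiration coefficient.
#' @param ks water-stress coefficient for transpiration.
#' @param ke soil-evaporation coefficient.
#' @param infil_max maximum daily infiltration, mm.
#' @return list with updated `soil` and a one-row `fluxes` tibble
#'   (precipitation, runoff, infiltration, percolation, es, tr,
#'   delta_storage, all mm).
#' @export
soil_water_step <- function(soil, precipitation, et0, cc, kcb, ks = 1,
                            ke = 1.1, infil_max = 50) {
  stopifnot(inherits(soil, "soil_profile"), precipitation >= 0, et0 >= 0)
  es_dem <- (1 - cc / 100) * ke * et0
  tr_dem <- transpiration(cc, kcb, et0, ks)
  st <- soil_step_raw(soil$theta, soil$thickness, soil$theta_fc,
                      soil$theta_wp, soil$theta_sat, precipitation,
                      es_dem, tr_dem, infil_max)
  soil$theta <- st$theta
  list(soil = soil, fluxes = tibble::as_tibble(as.list(st$fluxes)))
}

# root-zone water-stress coefficient from depletion
ks_from_soil <- function(theta, thick, fc, wp, p = 0.5) {
  taw <- sum((fc - wp) * thick) * 1000
  dr <- sum(pmax(0, fc - theta) * thick) * 1000
  raw <- p * taw
  if (dr <= raw) 1 else max(0, (taw - dr) / (taw - raw))
}

#' Run the daily canopy / soil-water / biomass simulation
#'
#' Orchestrates thermal time, canopy development, the layered soil-water
#' balance, transpiration and water-driven biomass/yield over a weather
#' series. Fully deterministic. With `soil = NULL` the water balance is
#' skipped and the crop is unstressed (the default assimilation setting);
#' with a soil profile the ledger is tracked and, if
#' `config$water_limited = TRUE`, a depletion-based stress coefficient
#' feeds back on canopy expansion and transpiration.
#'
#' @param params [crop_params()].
#' @param weather tibble with `tmin`, `tmax`, `precipitation`, `et0`.
#' @param soil a [soil_profile()] or NULL.
#' @param config list of constants: `cgc` (canopy growth coefficient per
#'   GDD, default 0.003), `ke` (soil evaporation coefficient, 1.1),
#'   `infil_max` (mm/day, 50), `water_limited` (FALSE), `p_depletion`
#'   (readily-available-water fraction, 0.5).
#' @return an `aqp_sim`: list with `daily` tibble (day, tmean, gdd, cc, tr,
#'   es), `water` flux ledger tibble (or NULL), `soil_final`, `biomass`,
#'   `yield`, `params`, `config`.
#' @export
run_crop_model <- function(params, weather, soil = NULL, config = list()) {
  stopifnot(inherits(params, "crop_params"))
  need <- c("tmin", "tmax", "precipitation", "et0")
  if (!all(need %in% names(weather))) {
    abort(paste0("weather must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(weather$precipitation < 0) || any(weather$et0 < 0)) {
    abort("precipitation and et0 must be non-negative.")
  }
  cfg <- modifyList(list(cgc = 0.003, ke = 1.1, infil_max = 50,
                         water_limited = FALSE, p_depletion = 0.5), config)
  tt <- thermal_time(weather, params$tbase, params$tupper)
  n <- nrow(tt)

  if (is.null(soil)) {
    cc <- simulate_canopy(params, tt$gdd, tt$tmean, ks = 1, cgc = cfg$cgc)
    tr <- transpiration(cc, params$kcb, weather$et0)
    es <- (1 - cc / 100) * cfg$ke * weather$et0
    water <- NULL
    soil_final <- NULL
  } else {
    stopifnot(inherits(soil, "soil_profile"))
    theta <- soil$theta; thick <- soil$thickness
    fc <- soil$theta_fc; wpt <- soil$theta_wp; sat <- soil$theta_sat
    cc <- tr <- es <- ks_out <- numeric(n)
    flux <- matrix(NA_real_, n, 7)
    clock <- 0
    cc0 <- min(max(params$cc_ini * params$den / 5000, 1e-9), params$mcc)
    for (d in seq_len(n)) {
      ks <- if (cfg$water_limited) {
        ks_from_soil(theta, thick, fc, wpt, cfg$p_depletion)
      } else 1
      gate <- ks * as.numeric(tt$tmean[d] >= params$tmg)
      clock <- clock + tt$gdd[d] * gate
      cc_d <- canopy_curve(clock, cc0, params$mcc, cfg$cgc)
      es_dem <- (1 - cc_d / 100) * cfg$ke * weather$et0[d]
      tr_dem <- transpiration(cc_d, params$kcb, weather$et0[d], ks)
      st <- tryCatch(
        soil_step_raw(theta, thick, fc, wpt, sat,
                      weather$precipitation[d], es_dem, tr_dem,
                      cfg$infil_max),
        error = function(e) abort(paste0("soil-water step failed on day ", d,
                                         ": ", conditionMessage(e)))
      )
      theta <- st$theta
      cc[d] <- cc_d; tr[d] <- st$fluxes[["tr"]]; es[d] <- st$fluxes[["es"]]
      ks_out[d] <- ks
      flux[d, ] <- st$fluxes
    }
    colnames(flux) <- c("precipitation", "runoff", "infiltration",
                        "percolation", "es", "tr", "delta_storage")
    water <- tibble::as_tibble(as.data.frame(flux))
    water$day <- seq_len(n)
    water$ks <- ks_out
    soil_final <- soil
    soil_final$theta <- theta
  }

  by <- biomass_yield(tr, weather$et0, params$wp, params$hi)
  structure(
    list(daily = tibble::tibble(day = tt$day, tmean = tt$tmean, gdd = tt$gdd,
                                cc = cc, tr = tr, es = es),
         water = water, soil_final = soil_final,
         biomass = by$biomass, yield = by$yield,
         params = params, config = cfg),
    class = "aqp_sim"
  )
}

#' @export
print.aqp_sim <- function(x, ...) {
  cat("<aqp_sim> ", nrow(x$daily), " days; final CC ",
      round(x$daily$cc[nrow(x$daily)], 2), "%, biomass ",
      signif(x$biomass, 5), ", yield ", signif(x$yield, 5), "\n", sep = "")
  invisible(x)
}
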