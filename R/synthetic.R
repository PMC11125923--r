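# All generators take an explicit seed and restore the caller's RNG state,
# so no global random state leaks between pipeline stages.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Default vegetation and soil reflectance spectra
#'
#' Per-band mean reflectances typical of a healthy green canopy (strong
#' red absorption, strong NIR scattering) and of bare soil (monotonically
#' rising, brighter in the red). The contrast between the two — canopy
#' dark in the red band, bright in NIR — is what makes Otsu segmentation
#' of the red band meaningful.
#'
#' @name default_spectra
#' @return named numeric vector over bands blue, green, red, rededge, nir.
NULL

#' @rdname default_spectra
#' @export
veg_spectrum_default <- function() {
  c(blue = 0.03, green = 0.08, red = 0.04, rededge = 0.25, nir = 0.50)
}

#' @rdname default_spectra
#' @export
soil_spectrum_default <- function() {
  c(blue = 0.10, green = 0.15, red = 0.22, rededge = 0.28, nir = 0.32)
}

#' Specification of a synthetic row-crop scene
#'
#' Describes a striped (row-planted) two-component scene: canopy columns
#' recur with period `row_period` and nominal width `row_width`, pixel
#' reflectances are drawn around the vegetation or soil spectrum with
#' Gaussian noise clipped to \[0, 1\].
#'
#' @param width,height scene size in pixels.
#' @param row_period,row_width stripe geometry in pixels
#'   (`row_width <= row_period`).
#' @param target_coverage desired canopy fraction in \[0, 1\].
#' @param veg_spectrum,soil_spectrum per-band mean reflectance in \[0, 1\];
#'   vegetation must be darker than soil in the red band and brighter in
#'   NIR.
#' @param noise_sd pixel noise standard deviation, reflectance units.
#' @param seed integer RNG seed.
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(width = 64, height = 64, row_period = 16, row_width = 8,
                       target_coverage = 0.5,
                       veg_spectrum = veg_spectrum_default(),
                       soil_spectrum = soil_spectrum_default(),
                       noise_sd = 0.02, seed = 1) {
  stopifnot(width >= 1, height >= 1, row_period >= 1)
  if (!(row_width >= 0 && row_width <= row_period)) {
    abort("need 0 <= row_width <= row_period.")
  }
  if (!(target_coverage >= 0 && target_coverage <= 1)) {
    abort("target_coverage must lie in [0, 1].")
  }
  bands <- c("blue", "green", "red", "rededge", "nir")
  if (!all(bands %in% names(veg_spectrum)) || !all(bands %in% names(soil_spectrum))) {
    abort("spectra must name all five bands.")
  }
  if (any(veg_spectrum < 0 | veg_spectrum > 1) ||
      any(soil_spectrum < 0 | soil_spectrum > 1)) {
    abort("spectra must lie in [0, 1].")
  }
  if (!(veg_spectrum[["red"]] < soil_spectrum[["red"]])) {
    abort("vegetation must be darker than soil in the red band.")
  }
  if (!(veg_spectrum[["nir"]] > soil_spectrum[["nir"]])) {
    abort("vegetation must be brighter than soil in the NIR band.")
  }
  stopifnot(noise_sd >= 0)
  structure(list(width = width, height = height, row_period = row_period,
                 row_width = row_width, target_coverage = target_coverage,
                 veg_spectrum = veg_spectrum[bands],
                 soil_spectrum = soil_spectrum[bands],
                 noise_sd = noise_sd, seed = seed),
            class = "scene_spec")
}

# allocate canopy columns to stripe blocks: each block of `period` columns
# can host at most `row_width` canopy columns (and no more than its size)
allocate_canopy_columns <- function(width, period, row_width, n_needed) {
  starts <- seq(1, width, by = period)
  sizes <- pmin(period, width - starts + 1)
  caps <- pmin(row_width, sizes)
  if (n_needed > sum(caps)) {
    abort(paste0("infeasible geometry: stripes of width ", row_width,
                 " every ", period, " px can cover at most ",
                 round(sum(caps) / width, 3), " of the scene."))
  }
  alloc <- integer(length(starts))
  remaining <- n_needed
  while (remaining > 0) { # water-fill one column at a time, evenly
    for (b in seq_along(alloc)) {
      if (remaining == 0) break
      if (alloc[b] < caps[b]) {
        alloc[b] <- alloc[b] + 1L
        remaining <- remaining - 1L
      }
    }
  }
  cols <- logical(width)
  for (b in seq_along(alloc)) {
    if (alloc[b] > 0) cols[starts[b]:(starts[b] + alloc[b] - 1L)] <- TRUE
  }
  cols
}

#' Generate a synthetic multiband scene with known canopy mask
#'
#' Builds a five-band reflectance stack whose canopy pixels are drawn
#' around the vegetation spectrum and soil pixels around the soil
#' spectrum, with truncated Gaussian noise. Canopy pixels form vertical
#' stripes; the number of canopy columns is chosen so realized coverage is
#' within one column quantum of `target_coverage`. Deterministic under the
#' spec's seed.
#'
#' @param spec a [scene_spec()].
#' @return a `truth_bundle`: list with `stack` ([band_stack()]),
#'   `canopy_mask` (logical ground-truth matrix), `true_coverage` (%,
#'   exactly 100 * canopy pixels / valid pixels), `vi_means` (one-row
#'   tibble of whole-plot means of the ten indices) and `spec`.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width; h <- spec$height
  n_cols <- round_half_up(spec$target_coverage * w)
  cols <- allocate_canopy_columns(w, spec$row_period, spec$row_width, n_cols)
  mask <- matrix(rep(cols, each = h), nrow = h, ncol = w)
  bands <- with_seed(spec$seed, {
    lapply(setNames(nm = names(spec$veg_spectrum)), function(bn) {
      mu <- ifelse(mask, spec$veg_spectrum[[bn]], spec$soil_spectrum[[bn]])
      r <- mu + rnorm(h * w, sd = spec$noise_sd)
      matrix(pmin(1, pmax(0, r)), h, w)
    })
  })
  stack <- band_stack(bands)
  structure(
    list(stack = stack, canopy_mask = mask,
         true_coverage = 100 * sum(mask) / length(mask),
         vi_means = vi_table(stack), spec = spec),
    class = "truth_bundle"
  )
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("<truth_bundle> ", x$spec$height, "x", x$spec$width,
      " scene, true coverage ", round(x$true_coverage, 2), "%\n", sep = "")
  invisible(x)
}

#' Generate a synthetic daily weather series
#'
#' Sinusoidal seasonal cycles for temperature and reference
#' evapotranspiration (warm peak in mid-July) plus Gaussian noise, and
#' summer-concentrated stochastic precipitation. Defaults emulate a humid
#' subtropical tea-growing climate: summer mean near 26 deg C, winter mean
#' near 3 deg C, roughly half the annual rain in summer.
#'
#' @param n_days number of days (>= 1).
#' @param climate named list overriding any of: `t_mean` (annual mean deg C),
#'   `t_amp` (seasonal semi-amplitude), `t_range` (diurnal Tmax - Tmin),
#'   `t_noise_sd`, `peak_doy` (warmest day of year), `start_doy`,
#'   `precip_prob` (annual-mean wet-day probability), `precip_prob_amp`
#'   (seasonal modulation), `precip_mean` (mean wet-day rain, mm),
#'   `et0_mean`, `et0_amp`, `et0_noise_sd`.
#' @param seed integer RNG seed.
#' @return tibble with `day`, `doy`, `tmin`, `tmax`, `precipitation`, `et0`.
#' @export
make_weather <- function(n_days = 365, climate = list(), seed = 1) {
  stopifnot(n_days >= 1)
  cl <- modifyList(
    list(t_mean = 14.5, t_amp = 11.5, t_range = 8, t_noise_sd = 1.5,
         peak_doy = 196, start_doy = 1,
         precip_prob = 0.30, precip_prob_amp = 0.18, precip_mean = 9,
         et0_mean = 3, et0_amp = 1.8, et0_noise_sd = 0.3),
    climate
  )
  doy <- (cl$start_doy - 1 + seq_len(n_days) - 1) %% 365 + 1
  season <- cos(2 * pi * (doy - cl$peak_doy) / 365)
  with_seed(seed, {
    tmean <- cl$t_mean + cl$t_amp * season + rnorm(n_days, sd = cl$t_noise_sd)
    tmin <- tmean - cl$t_range / 2
    tmax <- tmean + cl$t_range / 2
    p_wet <- pmin(1, pmax(0, cl$precip_prob + cl$precip_prob_amp * season))
    wet <- runif(n_days) < p_wet
    precip <- ifelse(wet, stats::rgamma(n_days, shape = 1.2,
                                        scale = cl$precip_mean / 1.2), 0)
    et0 <- pmax(0.1, cl$et0_mean + cl$et0_amp * season +
                  rnorm(n_days, sd = cl$et0_noise_sd))
    tibble::tibble(day = seq_len(n_days), doy = doy, tmin = tmin, tmax = tmax,
                   precipitation = precip, et0 = et0)
  })
}

#' Generate a vegetation-index / canopy-coverage sample table
#'
#' Draws vegetation-index values and computes coverage from a known truth
#' model plus Gaussian noise, clipped to \[0, 100\]. For single-predictor
#' truth models the predictor is uniform on `x_range`; for multi-predictor
#' (PLSR-style) truths each predictor mixes a shared latent greenness with
#' an independent component, giving realistically correlated indices.
#'
#' @param n number of samples (>= 3).
#' @param model a `cc_regression` or `cc_plsr` truth model (see
#'   [cc_regression_model()], [cc_plsr_model()]).
#' @param noise_sd observation noise on coverage, CC percentage points.
#' @param seed integer RNG seed.
#' @param x_range range of the latent/predictor values.
#' @param mix weight of the shared latent component for multi-predictor
#'   truths (1 = perfectly collinear predictors, 0 = independent).
#' @param include_all_vis if TRUE, the remaining Table-of-ten indices not
#'   used by the truth model are added as independent noise columns (no
#'   coverage signal), handy for testing correlation screening.
#' @return tibble with column `cc` and one column per index.
#' @export
make_vi_cc_dataset <- function(n, model, noise_sd = 0, seed = 1,
                               x_range = c(0.2, 0.95), mix = 0.5,
                               include_all_vis = FALSE) {
  stopifnot(n >= 3, noise_sd >= 0)
  preds <- if (inherits(model, "cc_plsr")) model$predictors else model$predictor
  with_seed(seed, {
    if (length(preds) == 1L) {
      X <- tibble::tibble(!!preds := runif(n, x_range[1], x_range[2]))
    } else {
      u <- runif(n, x_range[1], x_range[2])
      X <- purrr::map_dfc(setNames(nm = preds), function(p) {
        v <- runif(n, x_range[1], x_range[2])
        mix * u + (1 - mix) * v
      })
    }
    cc <- predict(model, X) + rnorm(n, sd = noise_sd)
    out <- dplyr::bind_cols(tibble::tibble(cc = pmin(100, pmax(0, cc))), X)
    if (include_all_vis) {
      rest <- setdiff(vi_names(), preds)
      for (p in rest) out[[p]] <- runif(n, x_range[1], x_range[2])
    }
    out
  })
}

#' Generate noisy observed canopy-coverage trajectories
#'
#' Runs the crop simulator at known true parameters and samples the
#' simulated coverage at the requested days, adding Gaussian noise clipped
#' to \[0, mcc\]. This stands in for a remote-sensing-inverted coverage
#' series with known ground truth.
#'
#' @param true_params [crop_params()] generating the truth.
#' @param weather weather tibble (see [make_weather()]).
#' @param days integer day indices within the weather span.
#' @param noise_sd observation noise, CC percentage points.
#' @param seed integer RNG seed.
#' @param soil,config passed to [run_crop_model()].
#' @return tibble with `day`, `cc` (noisy observation) and `cc_true`.
#' @export
make_observations <- function(true_params, weather, days, noise_sd = 0,
                              seed = 1, soil = NULL, config = list()) {
  stopifnot(noise_sd >= 0)
  if (any(days < 1 | days > nrow(weather))) {
    abort("observation days fall outside the simulated horizon.")
  }
  sim <- run_crop_model(true_params, weather, soil = soil, config = config)
  cc_true <- sim$daily$cc[days]
  cc <- with_seed(seed, cc_true + rnorm(length(days), sd = noise_sd))
  tibble::tibble(day = as.integer(days),
                 cc = pmin(true_params$mcc, pmax(0, cc)),
                 cc_true = cc_true)
}
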