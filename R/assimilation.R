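#' Assimilate observed canopy coverage into the crop model
#'
#' Tunes the nine crop parameters within their bounds by particle swarm
#' optimization so the simulated coverage matches the observed
#' (remote-sensing-inverted) series at the observation days. Each fitness
#' evaluation runs the daily simulator at the particle's parameters and
#' scores the discrepancy at the observation days; simulator failures
#' penalize the particle with infinite fitness and the run continues.
#'
#' @param observations tibble with `day` (indices into the weather series)
#'   and `cc` (observed coverage, %).
#' @param weather weather tibble (see [make_weather()]).
#' @param soil optional [soil_profile()] passed to the simulator.
#' @param config list overriding any of: `n_particles` (60), `iterations`
#'   (40), `seed` (1), `omega` (0.72), `c1`/`c2` (1.49), `variant`
#'   (`"mare"`; see [cc_cost()]), `bounds` ([default_param_bounds()]),
#'   `plateau_tol` (NULL = fixed budget), plus simulator constants `cgc`,
#'   `ke`, `infil_max`, `water_limited`, `p_depletion`.
#' @return an `aqp_assimilation`: `best_params` ([crop_params()]),
#'   `fitness_trace` tibble, `sim` (the simulation at the best parameters),
#'   `cc_s` (simulated coverage at the observation days), `yield`,
#'   `evaluation` (see [evaluate()]) and `config`.
#' @export
assimilate <- function(observations, weather, soil = NULL, config = list()) {
  stopifnot(all(c("day", "cc") %in% names(observations)))
  if (any(observations$day < 1 | observations$day > nrow(weather))) {
    abort("observation days fall outside the weather horizon.")
  }
  cfg <- modifyList(
    list(n_particles = 60, iterations = 40, seed = 1,
         omega = 0.72, c1 = 1.49, c2 = 1.49, variant = "mare",
         bounds = default_param_bounds(), plateau_tol = NULL,
         cgc = 0.003, ke = 1.1, infil_max = 50,
         water_limited = FALSE, p_depletion = 0.5),
    config
  )
  sim_cfg <- cfg[c("cgc", "ke", "infil_max", "water_limited", "p_depletion")]
  days <- observations$day
  cc_r <- observations$cc
  fitness <- function(x) {
    p <- crop_params(cc_ini = x[["cc_ini"]], den = x[["den"]], mcc = x[["mcc"]],
                     wp = x[["wp"]], hi = x[["hi"]], kcb = x[["kcb"]],
                     tmg = x[["tmg"]], tupper = x[["tupper"]],
                     tbase = x[["tbase"]])
    sim <- run_crop_model(p, weather, soil = soil, config = sim_cfg)
    cc_cost(sim$daily$cc[days], cc_r, cfg$variant)
  }
  opt <- pso_optimize(fitness, cfg$bounds,
                      n_particles = cfg$n_particles,
                      iterations = cfg$iterations, seed = cfg$seed,
                      omega = cfg$omega, c1 = cfg$c1, c2 = cfg$c2,
                      plateau_tol = cfg$plateau_tol)
  bp <- as.list(opt$best_x)
  best_params <- crop_params(cc_ini = bp$cc_ini, den = bp$den, mcc = bp$mcc,
                             wp = bp$wp, hi = bp$hi, kcb = bp$kcb,
                             tmg = bp$tmg, tupper = bp$tupper,
                             tbase = bp$tbase)
  sim <- run_crop_model(best_params, weather, soil = soil, config = sim_cfg)
  cc_s <- sim$daily$cc[days]
  structure(
    list(best_params = best_params, best_f = opt$best_f,
         fitness_trace = opt$trace, sim = sim, cc_s = cc_s,
         observations = observations, yield = sim$yield,
         evaluation = evaluate(cc_s, cc_r), config = cfg),
    class = "aqp_assimilation"
  )
}

#' @export
print.aqp_assimilation <- function(x, ...) {
  cat("<aqp_assimilation> ", nrow(x$fitness_trace) - 1, " iterations, best ",
      x$config$variant, " = ", signif(x$best_f, 5),
      "; CC rmse vs observations = ", signif(x$evaluation$rmse, 4), "\n",
      sep = "")
  invisible(x)
}

#' Compare a calibrated run against the assimilated run
#'
#' Runs the simulator at fixed calibrated parameters and contrasts its
#' coverage (and optionally yield) accuracy against the assimilated
#' parameters, both scored against the same observations. The headline
#' number is the relative improvement in coverage RMSE.
#'
#' @param observations tibble with `day` and `cc` used for both scores;
#'   if it carries a `cc_true` column (synthetic truth) both runs are also
#'   scored against the truth.
#' @param calibrated_params [crop_params()] of the non-assimilated run.
#' @param assimilation an `aqp_assimilation` fitted on `observations` with
#'   the same weather and soil.
#' @param weather,soil the same inputs the assimilation used.
#' @param true_yield optional measured/true yield for a yield comparison.
#' @return list with `cc` (tibble: one evaluation row per model),
#'   `improvement_pct` (positive = assimilation lowers coverage RMSE) and
#'   `yield` (tibble, when `true_yield` given).
#' @export
compare_calibration_vs_assimilation <- function(observations, calibrated_params,
                                                assimilation, weather,
                                                soil = NULL,
                                                true_yield = NULL) {
  stopifnot(inherits(assimilation, "aqp_assimilation"))
  sim_cfg <- assimilation$config[c("cgc", "ke", "infil_max", "water_limited",
                                   "p_depletion")]
  cal <- run_crop_model(calibrated_params, weather, soil = soil,
                        config = sim_cfg)
  days <- observations$day
  obs_col <- if ("cc_true" %in% names(observations)) "cc_true" else "cc"
  ref <- observations[[obs_col]]
  ev_cal <- evaluate(cal$daily$cc[days], ref)
  ev_ass <- evaluate(assimilation$sim$daily$cc[days], ref)
  cc <- dplyr::bind_rows(
    dplyr::mutate(ev_cal, model = "calibrated", .before = 1),
    dplyr::mutate(ev_ass, model = "assimilated", .before = 1)
  )
  improvement <- if (ev_cal$rmse > 0) {
    100 * (ev_cal$rmse - ev_ass$rmse) / ev_cal$rmse
  } else 0
  out <- list(cc = cc, improvement_pct = improvement,
              reference = obs_col)
  if (!is.null(true_yield)) {
    out$yield <- tibble::tibble(
      model = c("calibrated", "assimilated", "reference"),
      yield = c(cal$yield, assimilation$yield, true_yield)
    )
  }
  out
}
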