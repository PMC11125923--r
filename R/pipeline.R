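#' Default end-to-end pipeline configuration
#'
#' All knobs of [run_pipeline()], with every source of randomness derived
#' from the single `seed`. The defaults describe the reference synthetic
#' scenario: a one-year daily weather series, twelve monthly scene
#' acquisitions, red-band Otsu extraction, correlation screening at 0.8,
#' the four regression families plus PLSR with LOO-RMSEP component choice,
#' and a 60-particle, 40-iteration swarm minimizing the mean absolute
#' relative coverage difference.
#'
#' @param seed master integer seed.
#' @return named list of configuration blocks.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    n_days = 365,
    climate = list(),
    truth = NULL, # NULL = seeded uniform draw within the central 90% of bounds
    scene = list(width = 64, height = 64, row_period = 16, row_width = 12,
                 noise_sd = 0.02),
    obs_days = "monthly", # every 30 days from day 15, up to 12 acquisitions

    imaging = list(band = "red", polarity = "canopy_below"),
    inversion = list(screen_threshold = 0.8, n_plsr_predictors = 3,
                     rmsep_predictors = 5),
    crop = list(cgc = 0.003, ke = 1.1, infil_max = 50, water_limited = FALSE,
                p_depletion = 0.5),
    pso = list(n_particles = 60, iterations = 40, omega = 0.72, c1 = 1.49,
               c2 = 1.49, variant = "mare", plateau_tol = NULL),
    bounds = default_param_bounds()
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_pipeline_config()].
#' Unknown keys are rejected. A `bounds` block, if present, is a mapping
#' `param: [init, lower, upper]`.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bounds)) {
    raw$bounds <- tibble::tibble(
      param = names(raw$bounds),
      init = unname(purrr::map_dbl(raw$bounds, 1)),
      lower = unname(purrr::map_dbl(raw$bounds, 2)),
      upper = unname(purrr::map_dbl(raw$bounds, 3))
    )
  }
  validate_pipeline_config(raw)
}

validate_pipeline_config <- function(config) {
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  for (blk in c("scene", "imaging", "inversion", "crop", "pso")) {
    bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(bad)) {
      abort(paste0("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", ")))
    }
  }
  cfg <- modifyList(defaults, config)
  stopifnot(cfg$n_days >= 1)
  if (identical(cfg$obs_days, "monthly")) {
    cfg$obs_days <- head(seq(min(15L, cfg$n_days), cfg$n_days, by = 30L), 12L)
  }
  if (!all(cfg$obs_days >= 1 & cfg$obs_days <= cfg$n_days)) {
    abort("obs_days must fall inside the simulated horizon.")
  }
  cfg
}

draw_truth_params <- function(bounds, seed) {
  u <- with_seed(seed, runif(nrow(bounds)))
  vals <- bounds$lower + (0.05 + 0.9 * u) * (bounds$upper - bounds$lower)
  names(vals) <- bounds$param
  crop_params(cc_ini = vals[["cc_ini"]], den = vals[["den"]],
              mcc = vals[["mcc"]], wp = vals[["wp"]], hi = vals[["hi"]],
              kcb = vals[["kcb"]], tmg = vals[["tmg"]],
              tupper = vals[["tupper"]], tbase = vals[["tbase"]])
}

#' Run the full synthetic assimilation pipeline
#'
#' Executes the stages in order — synthesize weather and truth, render
#' scenes at the acquisition days, extract coverage by Otsu segmentation,
#' compute vegetation indices, screen and fit the inversion suite, invert
#' coverage with the PLSR model, assimilate it into the crop model by PSO,
#' and compare against the non-assimilated (calibrated) run — writing every
#' tabular artifact as CSV plus a JSON manifest recording the configuration
#' hash and seeds. Rerunning with the same configuration reproduces all
#' numeric outputs. On a stage failure, partial outputs are preserved and
#' the manifest marks the failure point.
#'
#' @param config list from [default_pipeline_config()] /
#'   [load_pipeline_config()], or a YAML path.
#' @param out_dir output directory for artifacts.
#' @return (invisibly) a list with all stage results: `weather`,
#'   `truth_params`, `truth_sim`, `samples`, `screening`, `fits`, `rmsep`,
#'   `plsr`, `observations`, `assimilation`, `comparison`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- load_pipeline_config(config)
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = rlang::hash(cfg), seed = cfg$seed,
                   started = format(Sys.time(), tz = "UTC"),
                   stages = character(0), status = "running")
  res <- list(config = cfg)
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      manifest$status <<- paste0("failed at stage '", name, "'")
      manifest$error <<- conditionMessage(e)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    manifest$stages <<- c(manifest$stages, name)
    out
  }

  res$weather <- stage("weather", make_weather(cfg$n_days, cfg$climate,
                                               seed = cfg$seed + 1L))
  readr::write_csv(res$weather, file.path(out_dir, "weather.csv"))

  res$truth_params <- stage("truth", {
    if (is.null(cfg$truth)) draw_truth_params(cfg$bounds, cfg$seed + 2L)
    else do.call(crop_params, cfg$truth)
  })
  readr::write_csv(tibble::tibble(param = names(unlist(res$truth_params)),
                                  value = unname(unlist(res$truth_params))),
                   file.path(out_dir, "truth_params.csv"))

  res$truth_sim <- stage("simulate-truth",
                         run_crop_model(res$truth_params, res$weather,
                                        config = cfg$crop))
  readr::write_csv(res$truth_sim$daily, file.path(out_dir, "truth_daily.csv"))

  res$samples <- stage("extract-cc", {
    rows <- purrr::map(cfg$obs_days, function(d) {
      sp <- scene_spec(width = cfg$scene$width, height = cfg$scene$height,
                       row_period = cfg$scene$row_period,
                       row_width = cfg$scene$row_width,
                       target_coverage = res$truth_sim$daily$cc[d] / 100,
                       noise_sd = cfg$scene$noise_sd,
                       seed = cfg$seed + 100L + d)
      tb <- make_scene(sp)
      ext <- extract_coverage(tb$stack, band = cfg$imaging$band,
                              polarity = cfg$imaging$polarity)
      if (d == cfg$obs_days[1]) {
        write_mask_png(ext$mask[[1]], file.path(out_dir, "mask_day1.png"))
        write_band_stack(tb$stack, out_dir, "scene_day1")
      }
      dplyr::bind_cols(
        tibble::tibble(day = d, cc = ext$coverage,
                       cc_scene_truth = tb$true_coverage,
                       threshold = ext$threshold),
        tb$vi_means
      )
    })
    dplyr::bind_rows(rows)
  })
  readr::write_csv(res$samples, file.path(out_dir, "samples.csv"))

  res$screening <- stage("screen-vis",
                         screen_vis(res$samples,
                                    cfg$inversion$screen_threshold))
  readr::write_csv(res$screening, file.path(out_dir, "screening.csv"))

  res$fits <- stage("fit-inversion", {
    preds <- if (nrow(res$screening)) res$screening$vi else vi_names()
    fit_cc_regressions(res$samples, preds)
  })
  readr::write_csv(dplyr::select(res$fits, -"model"),
                   file.path(out_dir, "fit_table.csv"))

  res$rmsep <- stage("rmsep", {
    preds <- head(res$screening$vi, cfg$inversion$rmsep_predictors)
    rmsep_curve(res$samples, predictors = preds)
  })
  readr::write_csv(res$rmsep$curve, file.path(out_dir, "rmsep.csv"))

  res$plsr <- stage("fit-plsr", {
    preds <- head(res$screening$vi, cfg$inversion$n_plsr_predictors)
    fit_cc_plsr(res$samples, predictors = preds,
                n_components = min(res$rmsep$selected, length(preds)))
  })
  readr::write_csv(tidy(res$plsr), file.path(out_dir, "plsr_coefficients.csv"))

  res$observations <- stage("invert-cc", tibble::tibble(
    day = as.integer(cfg$obs_days),
    cc = predict(res$plsr, res$samples, clip = TRUE),
    cc_true = res$truth_sim$daily$cc[cfg$obs_days]
  ))
  readr::write_csv(res$observations, file.path(out_dir, "observations.csv"))

  res$assimilation <- stage("assimilate", assimilate(
    res$observations, res$weather,
    config = c(cfg$pso, cfg$crop, list(seed = cfg$seed + 3L,
                                       bounds = cfg$bounds))
  ))
  readr::write_csv(res$assimilation$fitness_trace,
                   file.path(out_dir, "fitness_trace.csv"))
  readr::write_csv(tidy(res$assimilation),
                   file.path(out_dir, "best_params.csv"))

  res$comparison <- stage("compare", {
    cal <- do.call(crop_params, as.list(setNames(cfg$bounds$init,
                                                 cfg$bounds$param)))
    compare_calibration_vs_assimilation(
      res$observations, cal, res$assimilation, res$weather,
      true_yield = res$truth_sim$yield
    )
  })
  readr::write_csv(res$comparison$cc, file.path(out_dir, "comparison_cc.csv"))
  readr::write_csv(res$comparison$yield,
                   file.path(out_dir, "comparison_yield.csv"))
  readr::write_csv(tibble::tibble(improvement_pct = res$comparison$improvement_pct),
                   file.path(out_dir, "improvement.csv"))

  manifest$status <- "complete"
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts of a run directory back into the four headline
#' tables: per-index correlations, the per-family fit table, the fitness
#' trace, and the calibrated-versus-assimilated comparison.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return an `aqp_report` list of tibbles with a printed summary.
#' @export
pipeline_report <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(paste0("'", run_dir, "' is not a pipeline run (no manifest)."))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else NULL
  }
  out <- structure(
    list(manifest = manifest,
         correlations = rd("screening.csv"),
         fit_table = rd("fit_table.csv"),
         fitness_trace = rd("fitness_trace.csv"),
         comparison = rd("comparison_cc.csv"),
         yield = rd("comparison_yield.csv"),
         improvement = rd("improvement.csv")),
    class = "aqp_report"
  )
  if (manifest$status != "complete") {
    warn(paste0("run is incomplete (", manifest$status, "); partial report."))
  }
  out
}

#' @export
print.aqp_report <- function(x, ...) {
  cat("== pipeline report (", x$manifest$status, ", seed ",
      x$manifest$seed, ") ==\n", sep = "")
  if (!is.null(x$correlations)) {
    cat("\n-- index/coverage correlations --\n"); print(x$correlations)
  }
  if (!is.null(x$fit_table)) {
    cat("\n-- inversion fit table --\n"); print(x$fit_table)
  }
  if (!is.null(x$fitness_trace)) {
    n <- nrow(x$fitness_trace)
    cat("\n-- fitness trace: ", n - 1, " iterations, final best ",
        signif(x$fitness_trace$gbest_f[n], 5), " --\n", sep = "")
  }
  if (!is.null(x$comparison)) {
    cat("\n-- calibrated vs assimilated coverage --\n"); print(x$comparison)
  }
  if (!is.null(x$improvement)) {
    cat("\ncoverage RMSE improvement: ",
        round(x$improvement$improvement_pct, 1), "%\n", sep = "")
  }
  invisible(x)
}
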