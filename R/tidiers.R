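#' Tidy and glance methods
#'
#' Broom-style summaries: `tidy()` returns one row per term/parameter,
#' `glance()` a one-row model summary.
#'
#' @param x a fitted `cc_regression`, `cc_plsr` or `aqp_assimilation`.
#' @param ... unused.
#' @return a tibble.
#' @name aquapso-tidiers
NULL

#' @rdname aquapso-tidiers
#' @export
tidy.cc_regression <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b),
                 family = x$family, predictor = x$predictor)
}

#' @rdname aquapso-tidiers
#' @export
glance.cc_regression <- function(x, ...) {
  tibble::tibble(family = x$family, predictor = x$predictor,
                 r2 = x$r2, rmse = x$rmse, n = x$n)
}

#' @rdname aquapso-tidiers
#' @export
tidy.cc_plsr <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$predictors),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname aquapso-tidiers
#' @export
glance.cc_plsr <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_predictors = length(x$predictors),
                 r2 = x$r2, rmse = x$rmse, n = x$n)
}

#' @rdname aquapso-tidiers
#' @export
tidy.aqp_assimilation <- function(x, ...) {
  bounds <- x$config$bounds
  est <- unlist(x$best_params)[bounds$param]
  tibble::tibble(term = bounds$param, estimate = unname(est),
                 init = bounds$init, lower = bounds$lower,
                 upper = bounds$upper)
}

#' @rdname aquapso-tidiers
#' @export
glance.aqp_assimilation <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(best_f = x$best_f, variant = x$config$variant,
                   n_particles = x$config$n_particles,
                   iterations = nrow(x$fitness_trace) - 1L,
                   yield = x$yield),
    x$evaluation
  )
}

#' @rdname aquapso-tidiers
#' @export
tidy.aqp_sim <- function(x, ...) x$daily

#' @rdname aquapso-tidiers
#' @export
glance.aqp_sim <- function(x, ...) {
  tibble::tibble(n_days = nrow(x$daily),
                 cc_final = x$daily$cc[nrow(x$daily)],
                 cc_max = max(x$daily$cc),
                 total_tr = sum(x$daily$tr), total_es = sum(x$daily$es),
                 biomass = x$biomass, yield = x$yield)
}
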