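#' Pearson correlation coefficient
#'
#' The quotient of covariance and the two standard deviations. Errors on
#' degenerate input rather than returning NA.
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("need at least 3 observations.")
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) abort("zero variance; correlation undefined.")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
  min(1, max(-1, r))
}

#' Screen vegetation indices by correlation with coverage
#'
#' Computes the Pearson correlation of every index column against measured
#' coverage and keeps those with `|r| >= threshold`, sorted by `|r|`
#' descending. The default threshold 0.8 keeps the highly correlated band.
#'
#' @param samples tibble with a coverage column and index columns named
#'   after [vi_names()].
#' @param threshold minimum absolute correlation.
#' @param response name of the coverage column (default `"cc"`).
#' @return tibble with `vi`, `r`, `abs_r`, filtered and sorted; zero rows
#'   (with a warning) when nothing passes.
#' @export
screen_vis <- function(samples, threshold = 0.8, response = "cc") {
  if (!response %in% names(samples)) {
    abort(paste0("samples lack the response column '", response, "'."))
  }
  vis <- intersect(vi_names(), names(samples))
  if (length(vis) == 0L) abort("samples contain no vegetation-index columns.")
  out <- tibble::tibble(
    vi = vis,
    r = purrr::map_dbl(vis, ~ pearson(samples[[.x]], samples[[response]]))
  )
  out$abs_r <- abs(out$r)
  out <- dplyr::arrange(dplyr::filter(out, .data$abs_r >= threshold),
                        dplyr::desc(.data$abs_r))
  if (nrow(out) == 0L) {
    warn(paste0("no index reaches |r| >= ", threshold, "; returning zero rows."))
  }
  out
}

.reg_families <- c("linear", "logarithmic", "exponential", "power")

#' Construct a coverage regression model from known coefficients
#'
#' Builds a `cc_regression` directly from coefficients, e.g. a published
#' inversion equation, without fitting. Families: linear `y = a + b x`,
#' logarithmic `y = a + b ln x`, exponential `y = a e^(b x)`, power
#' `y = a x^b`.
#'
#' @param family one of `"linear"`, `"logarithmic"`, `"exponential"`,
#'   `"power"`.
#' @param a,b coefficients.
#' @param predictor name of the vegetation index the model maps from.
#' @return a `cc_regression` object.
#' @export
cc_regression_model <- function(family, a, b, predictor = "x") {
  family <- match.arg(family, .reg_families)
  structure(list(family = family, a = a, b = b, predictor = predictor,
                 r2 = NA_real_, rmse = NA_real_, n = NA_integer_),
            class = "cc_regression")
}

#' Fit a coverage regression of one of four families
#'
#' Linear and logarithmic families are fit by ordinary least squares on
#' `x` or `ln x`. Exponential and power families are fit by
#' log-linearization: least squares of `ln y` on `x` or `ln x`, a
#' deterministic convention (no iterative refinement by default). Set
#' `nls_refine = TRUE` to polish exponential/power fits by nonlinear least
#' squares started from the log-linear estimate. In-sample R2 and RMSE are
#' computed on the original response scale.
#'
#' @param data tibble holding predictor and response columns, or NULL when
#'   `x`/`y` vectors are given directly.
#' @param predictor predictor column name (or vector when `data` is NULL).
#' @param family regression family.
#' @param response response column name (default `"cc"`).
#' @param nls_refine polish exp/power fits with [stats::nls()].
#' @return a `cc_regression` with coefficients `a`, `b` and fit metrics.
#' @export
fit_cc_regression <- function(data, predictor, family = "linear",
                              response = "cc", nls_refine = FALSE) {
  family <- match.arg(family, .reg_families)
  if (is.data.frame(data)) {
    x <- data[[predictor]]; y <- data[[response]]; pname <- predictor
  } else {
    x <- predictor; y <- response; pname <- "x"
    if (!is.numeric(y)) abort("with vector input, pass y as `response`.")
  }
  if (length(x) < 3) abort("need at least 3 observations.")
  if (family %in% c("logarithmic", "power") && any(x <= 0)) {
    abort(paste0(family, " family requires strictly positive predictor values."))
  }
  if (family %in% c("exponential", "power") && any(y <= 0)) {
    abort(paste0(family, " family requires strictly positive response values."))
  }
  fit <- switch(family,
    linear      = lm(y ~ x),
    logarithmic = lm(y ~ log(x)),
    exponential = lm(log(y) ~ x),
    power       = lm(log(y) ~ log(x))
  )
  cf <- coef(fit)
  ab <- switch(family,
    linear      = c(a = unname(cf[1]), b = unname(cf[2])),
    logarithmic = c(a = unname(cf[1]), b = unname(cf[2])),
    exponential = c(a = exp(unname(cf[1])), b = unname(cf[2])),
    power       = c(a = exp(unname(cf[1])), b = unname(cf[2]))
  )
  if (nls_refine && family %in% c("exponential", "power")) {
    form <- if (family == "exponential") y ~ a * exp(b * x) else y ~ a * x^b
    nl <- tryCatch(stats::nls(form, start = list(a = ab[["a"]], b = ab[["b"]])),
                   error = function(e) NULL)
    if (!is.null(nl)) ab <- c(a = coef(nl)[["a"]], b = coef(nl)[["b"]])
  }
  m <- cc_regression_model(family, ab[["a"]], ab[["b"]], pname)
  pred <- predict(m, x)
  ev <- evaluate(pred, y)
  m$r2 <- ev$r2; m$rmse <- ev$rmse; m$n <- length(x)
  m
}

#' Predict coverage from a fitted inversion model
#'
#' Applies the model formula. Output is the raw regression value; set
#' `clip = TRUE` to clamp to \[0, 100\].
#'
#' @param object a `cc_regression` or `cc_plsr`.
#' @param newdata numeric vector (single-predictor models) or a
#'   data frame / matrix with the required predictor columns.
#' @param clip clamp predictions to \[0, 100\]? Default FALSE.
#' @param ... unused.
#' @return numeric vector of coverage predictions, %.
#' @export
predict.cc_regression <- function(object, newdata, clip = FALSE, ...) {
  x <- if (is.data.frame(newdata)) {
    if (!object$predictor %in% names(newdata)) {
      abort(paste0("newdata lacks predictor '", object$predictor, "'."))
    }
    newdata[[object$predictor]]
  } else as.numeric(newdata)
  if (object$family %in% c("logarithmic", "power") && any(x <= 0)) {
    abort(paste0(object$family, " model is undefined for non-positive predictor values."))
  }
  y <- switch(object$family,
    linear      = object$a + object$b * x,
    logarithmic = object$a + object$b * log(x),
    exponential = object$a * exp(object$b * x),
    power       = object$a * x^object$b
  )
  if (clip) y <- pmin(100, pmax(0, y)) else y
}

#' Fit all regression families over a set of predictors
#'
#' @param data sample tibble with a coverage column and index columns.
#' @param predictors index names to fit.
#' @param families subset of the four families.
#' @param response coverage column name.
#' @return tibble with one row per (predictor, family): coefficients,
#'   in-sample `r2`/`rmse` and the model in a list-column. Family/predictor
#'   pairs whose domain constraints fail are dropped.
#' @export
fit_cc_regressions <- function(data, predictors, families = .reg_families,
                               response = "cc") {
  grid <- tidyr::expand_grid(predictor = predictors, family = families)
  rows <- purrr::pmap(grid, function(predictor, family) {
    m <- tryCatch(fit_cc_regression(data, predictor, family, response),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    tibble::tibble(predictor = predictor, family = family,
                   a = m$a, b = m$b, r2 = m$r2, rmse = m$rmse,
                   model = list(m))
  })
  dplyr::bind_rows(rows)
}

#' Evaluate predictions against observations
#'
#' Reports `rmse = sqrt(mean((S - M)^2))`, the standard coefficient of
#' determination `r2 = 1 - SS_res/SS_tot`, the Pearson correlation, and —
#' for completeness — `r2_ratio`, the variance ratio
#' `sum((M - Mbar)^2) / sum((S - Mbar)^2)`, an alternative statistic that
#' is sometimes printed in place of R2 but is not bounded by 1.
#'
#' @param pred simulated/predicted values S.
#' @param obs measured values M.
#' @return one-row tibble: `n`, `rmse`, `r2`, `r2_ratio`, `pearson_r`.
#'   With zero variance in `obs`, `r2` is NA with a warning.
#' @export
evaluate <- function(pred, obs) {
  if (length(pred) != length(obs)) abort("`pred` and `obs` must have equal length.")
  n <- length(obs)
  if (n < 2) abort("need at least 2 observations.")
  rmse <- sqrt(sum((pred - obs)^2) / n)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    warn("observations have zero variance; r2 undefined.")
    r2 <- NA_real_
    r2_ratio <- NA_real_
  } else {
    r2 <- 1 - sum((obs - pred)^2) / ss_tot
    denom <- sum((pred - mean(obs))^2)
    r2_ratio <- if (denom > 0) ss_tot / denom else NA_real_
  }
  pr <- tryCatch(pearson(pred, obs), error = function(e) NA_real_)
  tibble::tibble(n = n, rmse = rmse, r2 = r2, r2_ratio = r2_ratio, pearson_r = pr)
}
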