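# NIPALS PLS1 on centered/scaled predictors, centered response.
# Returns regression coefficients back-transformed to the original
# predictor space, so prediction is a plain affine map.
nipals_pls1 <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  if (k < 1 || k > p) abort("n_components must lie in [1, ncol(X)].")
  if (n < k + 1) abort("need at least n_components + 1 samples.")
  mx <- colMeans(X)
  sx <- apply(X, 2, sd)
  if (any(sx == 0)) abort("constant predictor column; rank-deficient input.")
  Xc <- sweep(sweep(X, 2, mx, "-"), 2, sx, "/")
  my <- mean(y)
  yc <- y - my
  W <- P <- matrix(0, p, k)
  q <- numeric(k)
  Xd <- Xc
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      abort("requested components exceed the rank of the predictor matrix.")
    }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pvec <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yc * t) / tt
    Xd <- Xd - tcrossprod(t, pvec)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
  }
  b_scaled <- W %*% solve(crossprod(P, W), q)
  beta <- drop(b_scaled) / sx
  intercept <- my - sum(beta * mx)
  list(coefficients = setNames(beta, colnames(X)), intercept = intercept)
}

#' Construct a PLSR coverage model from known coefficients
#'
#' Builds a `cc_plsr` directly from an affine equation in original index
#' space (intercept plus one weight per index), e.g. a published
#' multi-index inversion equation.
#'
#' @param coefficients named numeric vector, one weight per index.
#' @param intercept scalar intercept.
#' @return a `cc_plsr` object.
#' @export
cc_plsr_model <- function(coefficients, intercept) {
  if (is.null(names(coefficients))) abort("`coefficients` must be named.")
  structure(list(predictors = names(coefficients),
                 coefficients = coefficients, intercept = intercept,
                 n_components = length(coefficients),
                 rmsep_curve = NULL, r2 = NA_real_, rmse = NA_real_,
                 n = NA_integer_),
            class = "cc_plsr")
}

#' Fit a partial least squares regression of coverage on indices
#'
#' NIPALS PLS1 with predictors centered and scaled internally; the final
#' coefficients are back-transformed so prediction is
#' `intercept + sum(coefficient * index)` in original index space. With
#' `n_components` equal to the number of predictors (full rank), the fit
#' coincides with ordinary least squares.
#'
#' @param data tibble holding the predictor and response columns, or a
#'   numeric matrix of predictors.
#' @param predictors index column names (default: all of [vi_names()]
#'   present). Ignored when `data` is a matrix.
#' @param n_components number of latent components.
#' @param response response column name, or the response vector when
#'   `data` is a matrix.
#' @return a `cc_plsr` with coefficients, intercept and in-sample metrics.
#' @export
fit_cc_plsr <- function(data, predictors = NULL, n_components = NULL,
                        response = "cc") {
  if (is.matrix(data)) {
    X <- data
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    y <- response
    if (!is.numeric(y) || length(y) != nrow(X)) {
      abort("with matrix input, pass the response vector as `response`.")
    }
  } else {
    predictors <- predictors %||% intersect(vi_names(), names(data))
    if (length(predictors) < 1) abort("no predictor columns found.")
    X <- as.matrix(data[predictors])
    y <- data[[response]]
  }
  k <- n_components %||% ncol(X)
  fit <- nipals_pls1(X, y, k)
  m <- cc_plsr_model(fit$coefficients, fit$intercept)
  m$n_components <- k
  pred <- predict(m, X)
  ev <- evaluate(pred, y)
  m$r2 <- ev$r2; m$rmse <- ev$rmse; m$n <- nrow(X)
  m
}

#' @rdname predict.cc_regression
#' @export
predict.cc_plsr <- function(object, newdata, clip = FALSE, ...) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$predictors, names(newdata))
    if (length(missing)) {
      abort(paste0("newdata lacks predictor(s): ", paste(missing, collapse = ", ")))
    }
    X <- as.matrix(newdata[object$predictors])
  } else if (is.matrix(newdata)) {
    X <- newdata[, object$predictors, drop = FALSE]
  } else {
    if (length(object$predictors) != 1) {
      abort("vector newdata only valid for single-predictor models.")
    }
    X <- matrix(as.numeric(newdata), ncol = 1,
                dimnames = list(NULL, object$predictors))
  }
  y <- drop(X %*% object$coefficients) + object$intercept
  if (clip) pmin(100, pmax(0, y)) else y
}

#' Cross-validated RMSEP over PLSR component counts
#'
#' Leave-one-out root mean square error of prediction for component counts
#' `1..k_max`. The selected count is the smallest at which RMSEP stops
#' decreasing (the first local minimum): adding components past it buys no
#' predictive accuracy.
#'
#' @param data tibble or predictor matrix (see [fit_cc_plsr()]).
#' @param predictors,response as in [fit_cc_plsr()].
#' @param k_max maximum component count (default: number of predictors).
#' @return list with `curve` (tibble `k`, `rmsep`) and `selected`.
#' @export
rmsep_curve <- function(data, predictors = NULL, k_max = NULL,
                        response = "cc") {
  if (is.matrix(data)) {
    X <- data
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    y <- response
  } else {
    predictors <- predictors %||% intersect(vi_names(), names(data))
    X <- as.matrix(data[predictors])
    y <- data[[response]]
  }
  n <- nrow(X)
  if (n < 4) abort("need at least 4 samples for cross-validation.")
  k_max <- k_max %||% ncol(X)
  k_max <- min(k_max, ncol(X), n - 2)
  err2 <- matrix(NA_real_, n, k_max)
  for (i in seq_len(n)) {
    for (k in seq_len(k_max)) {
      fit <- tryCatch(nipals_pls1(X[-i, , drop = FALSE], y[-i], k),
                      error = function(e) NULL)
      if (is.null(fit)) next
      pred <- sum(X[i, ] * fit$coefficients) + fit$intercept
      err2[i, k] <- (pred - y[i])^2
    }
  }
  rmsep <- sqrt(colMeans(err2, na.rm = TRUE))
  cmp <- ifelse(is.finite(rmsep), rmsep, Inf) # failed refits never get selected
  sel <- k_max
  for (k in seq_len(k_max - 1)) {
    if (cmp[k + 1] >= cmp[k]) { sel <- k; break }
  }
  list(curve = tibble::tibble(k = seq_len(k_max), rmsep = rmsep),
       selected = sel)
}
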