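#' Discrepancy between simulated and observed coverage series
#'
#' Three variants: `"mare"` (default objective) is the mean absolute
#' relative difference `mean(|CC_s - CC_r| / CC_s)`; `"signed_mre"` is
#' the signed mean relative difference `mean((CC_s - CC_r) / CC_s)`, whose
#' positive and negative errors cancel — kept selectable for comparison but
#' unsuitable as a minimization objective; `"rmse"` is the root mean
#' square error between the two series.
#'
#' @param cc_s simulated coverage at the observation dates, %.
#' @param cc_r observed (remote-sensing-inverted) coverage, %.
#' @param variant one of `"mare"`, `"signed_mre"`, `"rmse"`.
#' @return scalar cost.
#' @export
cc_cost <- function(cc_s, cc_r, variant = c("mare", "signed_mre", "rmse")) {
  variant <- match.arg(variant)
  if (length(cc_s) != length(cc_r) || length(cc_s) < 1) {
    abort("series must have equal length >= 1.")
  }
  if (variant != "rmse" && any(cc_s == 0)) {
    abort("relative cost undefined: simulated coverage is 0 at an observation.")
  }
  switch(variant,
    mare = mean(abs((cc_s - cc_r) / cc_s)),
    signed_mre = mean((cc_s - cc_r) / cc_s),
    rmse = sqrt(mean((cc_s - cc_r)^2))
  )
}

#' Initialize a particle swarm over a bounded box
#'
#' Positions are uniform within the bounds; velocities uniform in plus or
#' minus the coordinate range width. A degenerate coordinate
#' (`lower == upper`) stays fixed with zero velocity. Deterministic under
#' the seed.
#'
#' @param bounds tibble with columns `param`, `lower`, `upper` (e.g.
#'   [default_param_bounds()]).
#' @param n_particles swarm size (>= 2).
#' @param seed integer RNG seed.
#' @param omega inertia weight.
#' @param c1,c2 individual and group learning factors.
#' @return a `swarm` object.
#' @export
init_swarm <- function(bounds, n_particles = 60, seed = 1,
                       omega = 0.72, c1 = 1.49, c2 = 1.49) {
  stopifnot(n_particles >= 2, all(c("param", "lower", "upper") %in% names(bounds)))
  lo <- bounds$lower; hi <- bounds$upper
  if (any(hi < lo)) abort("bounds must satisfy lower <= upper.")
  d <- length(lo)
  rng <- hi - lo
  xs <- with_seed(seed, {
    x <- matrix(runif(n_particles * d), n_particles, d)
    v <- matrix(runif(n_particles * d, -1, 1), n_particles, d)
    list(x = sweep(sweep(x, 2, rng, "*"), 2, lo, "+"),
         v = sweep(v, 2, rng, "*"))
  })
  fixed <- rng == 0
  if (any(fixed)) {
    xs$x[, fixed] <- matrix(lo[fixed], n_particles, sum(fixed), byrow = TRUE)
    xs$v[, fixed] <- 0
  }
  colnames(xs$x) <- colnames(xs$v) <- bounds$param
  structure(
    list(x = xs$x, v = xs$v,
         pbest_x = xs$x, pbest_f = rep(Inf, n_particles),
         gbest_x = xs$x[1, ], gbest_f = Inf,
         omega = omega, c1 = c1, c2 = c2,
         lower = setNames(lo, bounds$param), upper = setNames(hi, bounds$param),
         evaluated = FALSE, iteration = 0L),
    class = "swarm"
  )
}

# evaluate all particles, update pbest/gbest (argmin rules)
swarm_evaluate <- function(swarm, fitness) {
  f <- vapply(seq_len(nrow(swarm$x)), function(i) {
    val <- tryCatch(fitness(swarm$x[i, ]), error = function(e) Inf)
    if (!is.finite(val)) Inf else val # invalid evaluations leave pbest unchanged
  }, numeric(1))
  better <- f < swarm$pbest_f
  swarm$pbest_f[better] <- f[better]
  swarm$pbest_x[better, ] <- swarm$x[better, , drop = FALSE]
  b <- which.min(swarm$pbest_f)
  if (swarm$pbest_f[b] < swarm$gbest_f) {
    swarm$gbest_f <- swarm$pbest_f[b]
    swarm$gbest_x <- swarm$pbest_x[b, ]
  }
  swarm$evaluated <- TRUE
  swarm
}

#' Advance the swarm one iteration
#'
#' Velocity and position update with inertia plus attraction toward the
#' personal and global bests, with fresh uniform random factors per
#' particle and dimension:
#' `v <- omega v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, `x <- x + v`.
#' Velocities are clamped to the coordinate range width; positions are
#' clipped to the bounds with the velocity zeroed on clipped coordinates.
#' Personal and global bests are then updated as fitness argmins, so the
#' global best fitness never increases.
#'
#' @param swarm a `swarm` from [init_swarm()]. On the first call the
#'   initial positions are evaluated before moving.
#' @param fitness function mapping a named parameter vector to a scalar
#'   cost; non-finite values are treated as failed evaluations.
#' @return the updated swarm.
#' @export
swarm_step <- function(swarm, fitness) {
  stopifnot(inherits(swarm, "swarm"))
  if (!swarm$evaluated) swarm <- swarm_evaluate(swarm, fitness)
  n <- nrow(swarm$x); d <- ncol(swarm$x)
  r1 <- matrix(runif(n * d), n, d)
  r2 <- matrix(runif(n * d), n, d)
  gb <- matrix(swarm$gbest_x, n, d, byrow = TRUE)
  v <- swarm$omega * swarm$v +
    swarm$c1 * r1 * (swarm$pbest_x - swarm$x) +
    swarm$c2 * r2 * (gb - swarm$x)
  vmax <- matrix(swarm$upper - swarm$lower, n, d, byrow = TRUE)
  v <- pmin(pmax(v, -vmax), vmax)
  x <- swarm$x + v
  lo <- matrix(swarm$lower, n, d, byrow = TRUE)
  hi <- matrix(swarm$upper, n, d, byrow = TRUE)
  clipped <- x < lo | x > hi
  x <- pmin(pmax(x, lo), hi)
  v[clipped] <- 0
  swarm$x <- x; swarm$v <- v
  swarm$iteration <- swarm$iteration + 1L
  swarm_evaluate(swarm, fitness)
}

#' Run a particle swarm optimization
#'
#' @param fitness function from a named parameter vector to scalar cost.
#' @param bounds tibble with `param`, `lower`, `upper`.
#' @param n_particles swarm size.
#' @param iterations number of update iterations (fixed budget, no early
#'   stop unless `plateau_tol` is set).
#' @param seed integer seed driving initialization and the per-step random
#'   factors.
#' @param omega,c1,c2 PSO coefficients.
#' @param plateau_tol optional early stop: halt when the relative change of
#'   the best fitness over `plateau_window` iterations falls below this.
#' @param plateau_window window for the plateau check.
#' @return list with `best_x` (named vector), `best_f`, `trace` (tibble
#'   `iteration`, `gbest_f`; iteration 0 is the evaluated initial swarm)
#'   and the final `swarm`.
#' @export
pso_optimize <- function(fitness, bounds, n_particles = 60, iterations = 40,
                         seed = 1, omega = 0.72, c1 = 1.49, c2 = 1.49,
                         plateau_tol = NULL, plateau_window = 5) {
  swarm <- init_swarm(bounds, n_particles, seed, omega, c1, c2)
  with_seed(seed + 1L, {
    swarm <- swarm_evaluate(swarm, fitness)
    trace <- numeric(iterations + 1)
    trace[1] <- swarm$gbest_f
    n_done <- 0L
    for (it in seq_len(iterations)) {
      swarm <- swarm_step(swarm, fitness)
      trace[it + 1] <- swarm$gbest_f
      n_done <- it
      if (!is.null(plateau_tol) && it > plateau_window) {
        prev <- trace[it + 1 - plateau_window]
        if (prev > 0 && (prev - trace[it + 1]) / prev < plateau_tol) break
      }
    }
    list(best_x = swarm$gbest_x, best_f = swarm$gbest_f,
         trace = tibble::tibble(iteration = 0:n_done,
                                gbest_f = trace[seq_len(n_done + 1)]),
         swarm = swarm)
  })
}
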