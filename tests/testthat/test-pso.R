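test_that("cost variants follow their definitions", {
  expect_equal(cc_cost(c(50, 60), c(50, 60), "mare"), 0)
  expect_equal(cc_cost(c(50, 60), c(50, 60), "signed_mre"), 0)
  expect_equal(cc_cost(c(50, 60), c(50, 60), "rmse"), 0)
  # signed errors cancel in the literal form but not in the absolute one
  expect_equal(cc_cost(c(50, 50), c(40, 60), "signed_mre"), 0)
  expect_equal(cc_cost(c(50, 50), c(40, 60), "mare"), 0.2)
  expect_equal(cc_cost(50, 45, "signed_mre"), 0.1)
  expect_error(cc_cost(c(0, 50), c(10, 50), "mare"), "coverage is 0")
  expect_equal(cc_cost(c(0, 50), c(10, 50), "rmse"), sqrt(50))
  expect_error(cc_cost(1:3, 1:2), "equal length")
})

test_that("swarm initialization is seeded, bounded, and handles fixed coords", {
  b <- default_param_bounds()
  s1 <- init_swarm(b, n_particles = 60, seed = 4)
  s2 <- init_swarm(b, n_particles = 60, seed = 4)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$v, s2$v)
  expect_equal(nrow(s1$x), 60)
  for (j in seq_len(nrow(b))) {
    expect_true(all(s1$x[, j] >= b$lower[j] & s1$x[, j] <= b$upper[j]))
    expect_true(all(abs(s1$v[, j]) <= b$upper[j] - b$lower[j]))
  }
  bd <- b
  bd$lower[3] <- bd$upper[3] <- 70
  sd <- init_swarm(bd, 10, seed = 1)
  expect_true(all(sd$x[, 3] == 70))
  expect_true(all(sd$v[, 3] == 0))
})

test_that("a swarm collapsed onto its best point is a fixed point", {
  b <- tibble::tibble(param = c("a", "b"), lower = c(0, 0), upper = c(1, 1))
  s <- init_swarm(b, 5, seed = 2)
  sphere <- function(x) sum((x - 0.5)^2)
  s <- aquapso:::swarm_evaluate(s, sphere)
  s$x <- matrix(s$gbest_x, 5, 2, byrow = TRUE,
                dimnames = list(NULL, b$param))
  s$pbest_x <- s$x
  s$pbest_f <- rep(sphere(s$gbest_x), 5)
  s$v <- matrix(0, 5, 2)
  set.seed(1)
  s2 <- swarm_step(s, sphere)
  expect_equal(s2$x, s$x)
  expect_equal(s2$gbest_f, s$gbest_f)
})

test_that("with pure social attraction particles move toward the best point", {
  b <- tibble::tibble(param = c("a", "b"), lower = c(-5, -5), upper = c(5, 5))
  sphere <- function(x) sum(x^2)
  s <- init_swarm(b, 20, seed = 3, omega = 0, c1 = 0, c2 = 1)
  s <- aquapso:::swarm_evaluate(s, sphere)
  x_old <- s$x
  g <- matrix(s$gbest_x, 20, 2, byrow = TRUE)
  set.seed(2)
  s2 <- swarm_step(s, sphere)
  # with omega = 0, c1 = 0, c2 = 1 and r2 <= 1, every coordinate ends
  # between its old value and the attractor
  lo <- pmin(x_old, g); hi <- pmax(x_old, g)
  expect_true(all(s2$x >= lo - 1e-12 & s2$x <= hi + 1e-12))
})

test_that("global best fitness never increases, for any seed", {
  b <- default_param_bounds()
  norm_sphere <- function(x) {
    z <- (x - b$lower) / (b$upper - b$lower)
    sum((z - 0.5)^2)
  }
  for (seed in 1:8) {
    out <- pso_optimize(norm_sphere, b, n_particles = 12, iterations = 15,
                        seed = seed)
    expect_true(all(diff(out$trace$gbest_f) <= 0), info = paste("seed", seed))
  }
})

test_that("the swarm solves the normalized sphere over the parameter box", {
  # the objective is evaluated in normalized coordinates because the raw
  # parameter scales span three orders of magnitude
  b <- default_param_bounds()
  norm_sphere <- function(x) {
    z <- (x - b$lower) / (b$upper - b$lower)
    sum((z - 0.4)^2) # optimum strictly inside the box
  }
  finals <- sapply(1:20, function(seed) {
    pso_optimize(norm_sphere, b, n_particles = 60, iterations = 40,
                 seed = seed)$best_f
  })
  expect_lte(median(finals), 1e-2)
})

test_that("non-finite fitness marks evaluations invalid without derailing", {
  b <- tibble::tibble(param = c("a", "b"), lower = c(0, 0), upper = c(1, 1))
  spiky <- function(x) if (x[1] > 0.8) NaN else sum((x - 0.2)^2)
  out <- pso_optimize(spiky, b, n_particles = 15, iterations = 20, seed = 5)
  expect_true(is.finite(out$best_f))
  expect_lt(out$best_f, 0.05)
})

test_that("every evaluated position stays inside the bounds", {
  b <- default_param_bounds()
  seen <- list()
  spy <- function(x) {
    seen[[length(seen) + 1]] <<- x
    sum(((x - b$lower) / (b$upper - b$lower) - 0.5)^2)
  }
  invisible(pso_optimize(spy, b, n_particles = 10, iterations = 10, seed = 9))
  X <- do.call(rbind, seen)
  for (j in seq_len(nrow(b))) {
    expect_true(all(X[, j] >= b$lower[j] & X[, j] <= b$upper[j]))
  }
})
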