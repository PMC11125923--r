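# Independent oracles and small fixtures used across the suite.

# exhaustive 256-candidate Otsu oracle: naive double loop, no shared code
# with otsu_threshold()
otsu_brute_force <- function(hist) {
  n <- sum(hist)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:255) {
    lo <- hist[seq_len(t + 1)]          # levels 0..t
    hi <- hist[seq(t + 2, 256)[seq_len(255 - t)]]
    n0 <- sum(lo); n1 <- n - n0
    if (n0 == 0 || n1 == 0) v <- 0
    else {
      mu0 <- sum(lo * 0:t) / n0
      mu1 <- sum(hi * (t + 1):255) / n1
      v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    }
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# random histograms with a variety of shapes
random_histogram <- function(seed) {
  set.seed(seed)
  shape <- sample(3, 1)
  h <- integer(256)
  if (shape == 1) { # two gaussian-ish modes
    m <- sort(sample(10:245, 2))
    x <- c(round(rnorm(400, m[1], sample(3:20, 1))),
           round(rnorm(400, m[2], sample(3:20, 1))))
    x <- x[x >= 0 & x <= 255]
    h <- tabulate(x + 1L, 256L)
  } else if (shape == 2) { # uniform sparse
    idx <- sample(256, sample(2:40, 1))
    h[idx] <- sample(1:50, length(idx), replace = TRUE)
  } else { # skewed counts everywhere
    h <- rpois(256, lambda = runif(1, 0.5, 8))
  }
  if (sum(h > 0) < 2) h[c(10, 200)] <- c(5L, 7L) # ensure two levels
  h
}

# a small scene bundle reused by imaging tests
tiny_scene <- function(coverage = 0.5, noise_sd = 0.02, seed = 7,
                       width = 64, height = 64, period = 16, rw = 12) {
  make_scene(scene_spec(width = width, height = height, row_period = period,
                        row_width = rw, target_coverage = coverage,
                        noise_sd = noise_sd, seed = seed))
}

quick_weather <- function(n = 120, seed = 3) make_weather(n, seed = seed)

# draw in-bounds crop parameters, uniform over the central share of the box
draw_params <- function(seed, central = 0.9) {
  b <- default_param_bounds()
  set.seed(seed)
  v <- b$lower + ((1 - central) / 2 + central * runif(nrow(b))) *
    (b$upper - b$lower)
  names(v) <- b$param
  crop_params(cc_ini = v[["cc_ini"]], den = v[["den"]], mcc = v[["mcc"]],
              wp = v[["wp"]], hi = v[["hi"]], kcb = v[["kcb"]],
              tmg = v[["tmg"]], tupper = v[["tupper"]], tbase = v[["tbase"]])
}

# daily water-balance closure residuals of a simulation ledger (mm)
closure_residuals <- function(sim) {
  w <- sim$water
  w$delta_storage - (w$precipitation - w$runoff - w$percolation - w$es - w$tr)
}
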