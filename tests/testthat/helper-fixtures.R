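# Shared fixtures built in code at test time.

# Gaussian mediation triple with known standardized paths:
# m = a*x + e_m, y = cprime*x + b*m + e_y, all marginal variances 1.
make_gauss_mediation <- function(n, a, b, cprime = 0, seed = 1) {
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    expr
  }
  withr_seed(seed, {
    x <- stats::rnorm(n)
    m <- a * x + sqrt(1 - a^2) * stats::rnorm(n)
    vy <- cprime^2 + b^2 + 2 * a * b * cprime
    if (vy >= 1) stop("paths too large for unit-variance outcome")
    y <- cprime * x + b * m + sqrt(1 - vy) * stats::rnorm(n)
    data.frame(x = x, m = m, y = y)
  })
}

# Small labelled atlas + matching random volume for aggregation tests
make_test_atlas <- function(seed = 1) {
  set.seed(seed)
  labels <- array(0L, dim = c(6, 5, 4))
  labels[1:2, , ] <- 1L
  labels[4:5, 1:3, ] <- 2L
  labels[6, , 1:2] <- 3L
  map <- data.frame(label = 1:3,
                    roi = c("L_SMG", "R_SMG", "L_AG"),
                    hemisphere = c("L", "R", "L"))
  atlas <- atlas_volume(labels, map, voxel_mm = c(2, 2, 2))
  vol <- volume3d(array(stats::rnorm(prod(dim(labels))), dim(labels)),
                  voxel_mm = c(2, 2, 2))
  list(atlas = atlas, vol = vol)
}

# Independent O(m^2) step-up FDR oracle (literal definition)
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- rank(p, ties.method = "first")[i]
    # smallest adjusted value over all j with p_j >= p_i at rank >= r
    cand <- vapply(seq_len(m), function(j) {
      rj <- rank(p, ties.method = "first")[j]
      if (rj >= r) p[j] * m / rj else Inf
    }, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}

# analytic bias-corrected one-sided p (CI-inversion closed form):
# direction +1 rejects when the BC lower bound exceeds 0
bc_p_oracle <- function(theta_hat, draws, direction) {
  B <- length(draws)
  clip <- function(p) pmin(pmax(p, 1 / (B + 1)), B / (B + 1))
  z0 <- qnorm(clip(mean(draws < theta_hat)))
  f0 <- clip(mean(draws < 0))
  if (direction > 0) {
    pnorm(qnorm(f0) - 2 * z0)
  } else {
    1 - pnorm(qnorm(f0) - 2 * z0)
  }
}
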