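test_that("a noise-free causal chain yields unit paths", {
  set.seed(1)
  n <- 400
  x <- rnorm(n)
  m <- x + 1e-3 * rnorm(n)   # numerically full-rank deterministic chain
  y <- m
  fp <- fit_paths(data.frame(x = x, m = m, y = y),
                  mediation_spec("x", "m", "y"))
  expect_equal(unname(fp$paths["a"]), 1, tolerance = 1e-4)
  expect_equal(unname(fp$paths["b"]), 1, tolerance = 1e-4)
  expect_equal(unname(fp$paths["c"]), 1, tolerance = 1e-4)
  expect_equal(unname(fp$paths["c_prime"]), 0, tolerance = 1e-4)
  expect_equal(unname(fp$paths["ab"]), 1, tolerance = 1e-4)
})

test_that("an orthogonal x-m pair gives a zero indirect effect exactly", {
  x <- rep(c(1, 1, -1, -1), 10)
  m <- rep(c(1, -1, 1, -1), 10)
  y <- m
  fp <- fit_paths(data.frame(x = x, m = m, y = y),
                  mediation_spec("x", "m", "y"))
  expect_lt(abs(fp$paths["a"]), 1e-12)
  expect_lt(abs(fp$paths["c"]), 1e-12)
  expect_equal(unname(fp$paths["b"]), 1, tolerance = 1e-12)
  expect_lt(abs(fp$paths["ab"]), 1e-12)
})

test_that("OLS paths match the closed-form normal-equations solution", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 60
    d <- data.frame(x = rnorm(n), m = rnorm(n), y = rnorm(n),
                    z1 = rnorm(n), z2 = rbinom(n, 1, 0.4))
    spec <- mediation_spec("x", "m", "y", covariates = c("z1", "z2"))
    fp <- fit_paths(d, spec)
    zs <- function(v) (v - mean(v)) / sd(v)
    xs <- zs(d$x); ms <- zs(d$m); ys <- zs(d$y)
    Z <- cbind(zs(d$z1), zs(d$z2))
    ne <- function(D, r) solve(t(D) %*% D, t(D) %*% r)
    a <- ne(cbind(1, xs, Z), ms)[2]
    cb <- ne(cbind(1, xs, ms, Z), ys)
    cc <- ne(cbind(1, xs, Z), ys)[2]
    expect_equal(unname(fp$paths["a"]), a, tolerance = 1e-10)
    expect_equal(unname(fp$paths["c_prime"]), cb[2], tolerance = 1e-10)
    expect_equal(unname(fp$paths["b"]), cb[3], tolerance = 1e-10)
    expect_equal(unname(fp$paths["c"]), cc, tolerance = 1e-10)
    # effect decomposition holds exactly in OLS mode
    expect_lt(abs(fp$paths["c"] - fp$paths["c_prime"] - fp$paths["ab"]),
              1e-10)
    expect_lt(abs(fp$paths["ab"] - fp$paths["a"] * fp$paths["b"]), 1e-12)
  }
})

test_that("rank-deficient designs are rejected with the column named", {
  set.seed(2)
  d <- data.frame(x = rnorm(30), m = rnorm(30), y = rnorm(30))
  d$z1 <- 2 * d$x
  expect_error(fit_paths(d, mediation_spec("x", "m", "y", "z1")),
               "rank-deficient")
  expect_error(mediation_spec("x", "x", "y"), "distinct")
})

test_that("standardized paths are invariant to positive column rescaling", {
  d <- make_gauss_mediation(150, a = 0.4, b = 0.3, cprime = 0.2, seed = 17)
  set.seed(18)
  d$z1 <- rnorm(150)
  spec <- mediation_spec("x", "m", "y", covariates = "z1")
  p1 <- fit_paths(d, spec)$paths
  d2 <- transform(d, x = x * 13.7, m = m * 0.002, y = y * 5, z1 = z1 * 3)
  p2 <- fit_paths(d2, spec)$paths
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("sobel test matches its closed form", {
  s <- sobel_test(0, 0.5, 0.1, 0.1)
  expect_equal(s$z, 0)
  expect_equal(s$p, 1)
  s2 <- sobel_test(1, 1, 1, 1)
  expect_equal(s2$z, 1 / sqrt(2))
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(1); b <- rnorm(1); sa <- runif(1, 0.01, 1); sb <- runif(1, 0.01, 1)
    s3 <- sobel_test(a, b, sa, sb)
    z_ref <- a * b / sqrt(a^2 * sb^2 + b^2 * sa^2)
    expect_equal(s3$z, z_ref)
    expect_equal(s3$p, 2 * (1 - pnorm(abs(z_ref))))
  }
  expect_error(sobel_test(1, 1, 0, 1), "positive")
})

test_that("bisquare IRLS matches OLS on clean data and resists outliers", {
  set.seed(11)
  n <- 200
  X <- cbind(1, rnorm(n))
  y <- X %*% c(2, 1.5) + 0.05 * rnorm(n)
  fit_r <- irls_bisquare(y, X)
  fit_o <- lm.fit(X, as.vector(y))$coefficients
  expect_true(fit_r$converged)
  expect_lt(max(abs(fit_r$coefficients - fit_o)), 1e-3)

  # weights are exactly zero beyond the tuning radius
  y_out <- as.vector(y); y_out[1] <- y_out[1] + 1000
  fit_out <- irls_bisquare(y_out, X)
  expect_equal(fit_out$weights[1], 0)

  # one gross high-leverage outlier in 100 points: robust slope beats OLS
  wins <- 0
  for (s in 1:200) {
    set.seed(s)
    Xs <- cbind(1, rnorm(100))
    Xs[1, 2] <- 3
    ys <- Xs %*% c(0, 1) + rnorm(100)
    ys[1] <- 50
    b_r <- irls_bisquare(ys, Xs)$coefficients[2]
    b_o <- lm.fit(Xs, as.vector(ys))$coefficients[2]
    if (abs(b_r - 1) < abs(b_o - 1)) wins <- wins + 1
  }
  expect_gte(wins / 200, 0.95)
})

test_that("bisquare IRLS agrees with an independent robust fitter", {
  skip_if_not_installed("MASS")
  set.seed(23)
  n <- 150
  X <- cbind(1, rnorm(n), runif(n))
  y <- X %*% c(1, -2, 0.5) + rt(n, df = 3)
  ours <- irls_bisquare(y, X)$coefficients
  ref <- MASS::rlm(X, y, psi = MASS::psi.bisquare, c = 4.685,
                   scale.est = "MAD", maxit = 100)$coefficients
  expect_equal(unname(ours), unname(ref), tolerance = 5e-3)
})

test_that("bootstrap mediation is deterministic under a seed", {
  d <- make_gauss_mediation(120, a = 0.5, b = 0.4, seed = 4)
  spec <- mediation_spec("x", "m", "y", n_boot = 200, seed = 42)
  r1 <- bootstrap_mediation(d, spec)
  r2 <- bootstrap_mediation(d, spec)
  expect_identical(r1, r2)
  spec2 <- mediation_spec("x", "m", "y", n_boot = 200, seed = 43)
  expect_false(identical(bootstrap_mediation(d, spec2)$boot_mean_ab,
                         r1$boot_mean_ab))
})

test_that("bias-corrected p-values agree with the analytic inversion", {
  d <- make_gauss_mediation(250, a = 0.3, b = 0.15, seed = 8)
  spec <- mediation_spec("x", "m", "y", n_boot = 2000, seed = 5,
                         tails = "one", expected_sign_ab = "+")
  res <- bootstrap_mediation(d, spec)
  # reconstruct the draws deterministically and apply the closed form
  pd <- data.frame(x = d$x, m = d$m, y = d$y)
  fp <- fit_paths(pd, spec)
  set.seed(5)
  draws <- replicate(2000, {
    idx <- sample.int(250, 250, replace = TRUE)
    db <- pd[idx, ]
    zs <- function(v) (v - mean(v)) / sd(v)
    a <- coef(lm(zs(db$m) ~ zs(db$x)))[2]
    b <- coef(lm(zs(db$y) ~ zs(db$x) + zs(db$m)))[3]
    a * b
  })
  p_oracle <- bc_p_oracle(fp$paths["ab"], draws, +1)
  expect_lt(abs(res$p_ab - p_oracle), 0.02)
})

test_that("a result opposite to the declared direction is not significant", {
  d <- make_gauss_mediation(300, a = 0.5, b = 0.5, seed = 6)  # ab > 0
  spec <- mediation_spec("x", "m", "y", n_boot = 400, seed = 7,
                         tails = "one", expected_sign_ab = "-")
  res <- bootstrap_mediation(d, spec)
  expect_gte(res$p_ab, 0.5)
})

test_that("mostly-degenerate resamples abort with a diagnostic", {
  d <- data.frame(x = c(1, rep(0, 9)), m = rnorm(10), y = rnorm(10))
  spec <- mediation_spec("x", "m", "y", n_boot = 100, seed = 3)
  expect_error(bootstrap_mediation(d, spec), "10%")
})

test_that("listwise deletion drops incomplete rows", {
  d <- make_gauss_mediation(100, a = 0.4, b = 0.4, seed = 12)
  d$y[c(3, 50)] <- NA
  fp <- fit_paths(d, mediation_spec("x", "m", "y"))
  expect_equal(fp$n_used, 98)
})
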