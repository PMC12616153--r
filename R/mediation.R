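#' Specify a three-variable mediation model
#'
#' Defines the X -> M -> Y path model with nuisance covariates. The five
#' paths are: a (M ~ X), b and c' (Y ~ X + M; b is the M slope, c' the
#' direct effect), c (Y ~ X, total effect), and the indirect effect
#' ab = a * b. All three regressions include an intercept and the same
#' covariates, so in ordinary-least-squares mode c = c' + ab exactly.
#' X, M and Y are z-scored on the analysis sample, making every path a
#' standardized coefficient.
#'
#' @param x_name,m_name,y_name Column names of the independent variable,
#'   mediator, and outcome; must be distinct.
#' @param covariates Character vector of nuisance covariate columns.
#' @param n_boot Bootstrap resamples (default 5000).
#' @param alpha Significance level (default 0.05).
#' @param tails "one" (default, directional hypothesis) or "two".
#' @param expected_sign_ab "+" or "-": the a-priori direction of the
#'   indirect effect for one-tailed testing. `NULL` (default) falls back to
#'   the sign of the point estimate; declare it explicitly for confirmatory
#'   analyses.
#' @param robust Fit each regression by iteratively reweighted least
#'   squares with Tukey bisquare weights instead of OLS.
#' @param seed Integer seed making the bootstrap reproducible.
#' @param fixed_scaling Reuse the full-sample centers/scales of X, M, Y
#'   inside each resample instead of re-z-scoring (default `FALSE`:
#'   standardization is treated as part of the estimator).
#' @param tuning,max_iter,tol Bisquare tuning constant and IRLS stopping
#'   rule (see [irls_bisquare()]).
#' @return A `mediation_spec` list.
#' @export
mediation_spec <- function(x_name, m_name, y_name,
                           covariates = character(),
                           n_boot = 5000, alpha = 0.05,
                           tails = c("one", "two"),
                           expected_sign_ab = NULL,
                           robust = FALSE, seed = NULL,
                           fixed_scaling = FALSE,
                           tuning = 4.685, max_iter = 50, tol = 1e-6) {
  tails <- match.arg(tails)
  vars <- c(x_name, m_name, y_name, covariates)
  if (anyDuplicated(vars)) {
    stop("x, m, y and covariates must name distinct columns", call. = FALSE)
  }
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  if (!is.null(expected_sign_ab) &&
      !expected_sign_ab %in% c("+", "-")) {
    stop('expected_sign_ab must be "+", "-", or NULL', call. = FALSE)
  }
  structure(list(x_name = x_name, m_name = m_name, y_name = y_name,
                 covariates = covariates, n_boot = as.integer(n_boot),
                 alpha = alpha, tails = tails,
                 expected_sign_ab = expected_sign_ab, robust = robust,
                 seed = seed, fixed_scaling = fixed_scaling,
                 tuning = tuning, max_iter = max_iter, tol = tol),
            class = "mediation_spec")
}

# ---- low-level fitting ----------------------------------------------------

#' Iteratively reweighted least squares with Tukey bisquare weights
#'
#' Robust linear regression: starting from OLS, residuals are scaled by
#' MAD/0.6745 and weighted by the bisquare function
#' `w(u) = (1 - u^2)^2` for `|u| < 1` (0 beyond), with
#' `u = r / (tuning * scale)`; iterate until the largest coefficient change
#' drops below `tol`.
#'
#' @param y Response vector.
#' @param X Design matrix (including the intercept column), full rank.
#' @param tuning Bisquare tuning constant; 4.685 gives 95% efficiency under
#'   Gaussian errors.
#' @param max_iter,tol Stopping rule.
#' @return List with `coefficients`, `weights`, `residuals`, `scale`,
#'   `iterations`, and logical `converged` (a warning is raised when the
#'   iteration limit is hit and the best iterate returned).
#' @export
irls_bisquare <- function(y, X, tuning = 4.685, max_iter = 50, tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.vector(y)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  if (anyNA(beta)) stop("design matrix is rank deficient", call. = FALSE)
  converged <- FALSE
  iter <- 0L
  w <- rep(1, length(y))
  for (iter in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    s <- stats::median(abs(r - stats::median(r))) / 0.6745
    if (s <= .Machine$double.eps * max(abs(y), 1)) {
      converged <- TRUE  # essentially exact fit
      break
    }
    u <- r / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(w == 0)) break
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    if (anyNA(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("IRLS did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  list(coefficients = beta, weights = w,
       residuals = y - drop(X %*% beta), scale = if (exists("s")) s else 0,
       iterations = iter, converged = converged)
}

# z-score by sample sd; returns NULL when degenerate (constant)
zsc <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(NULL)
  (v - mean(v)) / s
}

# fit the three path regressions; x, m, y already standardized,
# Z a covariate matrix (may have 0 columns). Returns the 5 paths or NULL on
# a degenerate fit.
paths_core <- function(x, m, y, Z, robust = FALSE, tuning = 4.685,
                       max_iter = 50, tol = 1e-6) {
  D1 <- cbind(1, x, Z)
  D2 <- cbind(1, x, m, Z)
  if (robust) {
    f <- function(dm, resp) {
      tryCatch(
        suppressWarnings(
          irls_bisquare(resp, dm, tuning, max_iter, tol)$coefficients),
        error = function(e) NULL)
    }
    ca <- f(D1, m); if (is.null(ca) || anyNA(ca)) return(NULL)
    cb <- f(D2, y); if (is.null(cb) || anyNA(cb)) return(NULL)
    cc_ <- f(D1, y); if (is.null(cc_) || anyNA(cc_)) return(NULL)
  } else {
    ca <- stats::.lm.fit(D1, m)$coefficients
    cb <- stats::.lm.fit(D2, y)$coefficients
    cc_ <- stats::.lm.fit(D1, y)$coefficients
    if (anyNA(ca) || anyNA(cb) || anyNA(cc_)) return(NULL)
  }
  a <- unname(ca[2]); c_prime <- unname(cb[2]); b <- unname(cb[3])
  cc <- unname(cc_[2])
  c(a = a, b = b, c = cc, c_prime = c_prime, ab = a * b)
}

# assemble aligned, complete-case analysis columns from a data frame
prepare_mediation_data <- function(data, spec) {
  vars <- c(spec$x_name, spec$m_name, spec$y_name, spec$covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("data is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(vars, function(v) as.numeric(data[[v]]))
  mat <- do.call(cbind, cols)
  colnames(mat) <- vars
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  n <- nrow(mat)
  n_pred <- 2L + length(spec$covariates)
  if (n < n_pred + 2L) {
    stop("too few complete rows for the mediation model", call. = FALSE)
  }
  Z <- mat[, spec$covariates, drop = FALSE]
  # z-score numeric covariates once (scale does not change standardized
  # paths; it only conditions the solve)
  if (ncol(Z) > 0) {
    Z <- apply(Z, 2, function(v) {
      s <- stats::sd(v)
      if (is.finite(s) && s > 0) (v - mean(v)) / s else v
    })
    Z <- matrix(Z, nrow = n,
                dimnames = list(NULL, spec$covariates))
  }
  # rank check on the full design, naming the offending columns
  full <- cbind(x = mat[, spec$x_name], m = mat[, spec$m_name], Z)
  qrd <- qr(cbind(1, full))
  if (qrd$rank < ncol(full) + 1L) {
    bad <- colnames(full)[qrd$pivot[seq(qrd$rank + 1, ncol(full) + 1)] - 1L]
    stop("rank-deficient design; collinear column(s): ",
         paste(stats::na.omit(bad), collapse = ", "), call. = FALSE)
  }
  list(x = mat[, spec$x_name], m = mat[, spec$m_name],
       y = mat[, spec$y_name], Z = Z, n = n)
}

#' Fit mediation path point estimates
#'
#' Z-scores X, M, Y on the complete-case analysis sample and fits the three
#' regressions (M ~ X + Z, Y ~ X + M + Z, Y ~ X + Z) by OLS or bisquare
#' IRLS, returning the five standardized paths. In OLS mode also returns
#' the standard errors of a and b for use with [sobel_test()].
#'
#' @param data Data frame holding the model columns.
#' @param spec A [mediation_spec()].
#' @return A list with `paths` (named vector a, b, c, c_prime, ab),
#'   `se_a`, `se_b` (OLS mode only, else `NA`), and `n_used`.
#' @export
fit_paths <- function(data, spec) {
  pd <- prepare_mediation_data(data, spec)
  x <- zsc(pd$x); m <- zsc(pd$m); y <- zsc(pd$y)
  if (is.null(x) || is.null(m) || is.null(y)) {
    stop("x, m and y must each be non-constant", call. = FALSE)
  }
  paths <- paths_core(x, m, y, pd$Z, spec$robust, spec$tuning,
                      spec$max_iter, spec$tol)
  if (is.null(paths)) stop("path model fit failed", call. = FALSE)
  se_a <- se_b <- NA_real_
  if (!spec$robust) {
    se_a <- ols_se(cbind(1, x, pd$Z), m)[2]
    seb <- ols_se(cbind(1, x, m, pd$Z), y)
    se_b <- seb[3]
  }
  list(paths = paths, se_a = se_a, se_b = se_b, n_used = pd$n)
}

# OLS coefficient standard errors via the QR decomposition
ols_se <- function(X, y) {
  qrd <- qr(X)
  res <- qr.resid(qrd, y)
  df <- nrow(X) - qrd$rank
  sigma2 <- sum(res^2) / df
  R <- qr.R(qrd)
  XtX_inv <- chol2inv(R)
  sqrt(diag(XtX_inv) * sigma2)[order(qrd$pivot)]
}

#' Sobel test for an indirect effect
#'
#' Large-sample normal-theory test of ab = 0:
#' `z = a*b / sqrt(a^2 * se_b^2 + b^2 * se_a^2)`, with a two-tailed normal
#' p-value. Used as an independent asymptotic check on the bootstrap.
#'
#' @param a,b Path estimates.
#' @param se_a,se_b Their standard errors (> 0).
#' @return List with `z` and `p`.
#' @export
sobel_test <- function(a, b, se_a, se_b) {
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be positive",
                                   call. = FALSE)
  denom <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  z <- if (denom == 0) 0 else a * b / denom
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# ---- bias-corrected bootstrap inference -----------------------------------

# BC bias-correction constant from the bootstrap draws
bc_z0 <- function(theta_hat, draws) {
  B <- length(draws)
  stats::qnorm(clip_prop(mean(draws < theta_hat), B))
}

# does the one-sided BC bound at level alpha exclude 0 in direction d?
# d = -1: reject when the BC upper bound < 0; d = +1: lower bound > 0
bc_excludes_zero <- function(draws, z0, alpha, d) {
  B <- length(draws)
  if (d < 0) {
    q <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
    stats::quantile(draws, clip_prop(q, B), type = 6, names = FALSE) < 0
  } else {
    q <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
    stats::quantile(draws, clip_prop(q, B), type = 6, names = FALSE) > 0
  }
}

# smallest alpha at which the one-sided BC bound excludes zero, by binary
# search to 1e-4 (the CI-inversion definition of the p-value)
bc_pvalue_one_sided <- function(draws, z0, d) {
  lo <- 1e-6; hi <- 1 - 1e-6
  if (!bc_excludes_zero(draws, z0, hi, d)) return(1)
  if (bc_excludes_zero(draws, z0, lo, d)) return(lo)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (bc_excludes_zero(draws, z0, mid, d)) hi <- mid else lo <- mid
  }
  hi
}

bc_pvalue <- function(theta_hat, draws, direction, tails) {
  z0 <- bc_z0(theta_hat, draws)
  if (tails == "one") {
    bc_pvalue_one_sided(draws, z0, direction)
  } else {
    min(1, 2 * min(bc_pvalue_one_sided(draws, z0, -1),
                   bc_pvalue_one_sided(draws, z0, +1)))
  }
}

# bias-corrected (not accelerated) percentile interval
bc_interval <- function(theta_hat, draws, level = 0.95) {
  B <- length(draws)
  z0 <- bc_z0(theta_hat, draws)
  a2 <- (1 - level) / 2
  lo_q <- stats::pnorm(2 * z0 + stats::qnorm(a2))
  hi_q <- stats::pnorm(2 * z0 + stats::qnorm(1 - a2))
  c(lower = stats::quantile(draws, clip_prop(lo_q, B), type = 6,
                            names = FALSE),
    upper = stats::quantile(draws, clip_prop(hi_q, B), type = 6,
                            names = FALSE))
}

#' Bootstrap mediation analysis with bias-corrected p-values
#'
#' Fits the path model on the analysis sample, then draws `n_boot`
#' nonparametric resamples of participants (rows, with replacement),
#' refitting the full estimator — including re-z-scoring of X, M, Y —
#' within each resample. For every path the bias-correction constant
#' `z0 = qnorm(#\{theta* < theta_hat\}/B)` shifts the percentile bounds,
#' and the p-value is the smallest alpha at which the bias-corrected
#' percentile bound excludes 0 (one-tailed in the expected direction; the
#' two-tailed p doubles the smaller one-sided value, capped at 1).
#' Proportions are clipped to `[1/(B+1), B/(B+1)]`. Resamples with a
#' degenerate fit (e.g. a constant column after resampling) are redrawn so
#' the number of effective resamples stays at `n_boot`; more than 10%
#' redraws aborts.
#'
#' @inheritParams fit_paths
#' @return A `mediation_result` list: standardized `beta_a`, `beta_b`,
#'   `beta_c`, `beta_c_prime`, `beta_ab`; p-values `p_a` ... `p_ab`;
#'   `n_used`, `n_boot_effective`, `n_redrawn`; the bootstrap mean and SD
#'   of the indirect effect (`boot_mean_ab`, `boot_sd_ab`); and the
#'   bias-corrected `(1 - alpha)` interval for ab (`ab_ci_lower`,
#'   `ab_ci_upper`).
#' @export
bootstrap_mediation <- function(data, spec) {
  pd <- prepare_mediation_data(data, spec)
  x0 <- zsc(pd$x); m0 <- zsc(pd$m); y0 <- zsc(pd$y)
  if (is.null(x0) || is.null(m0) || is.null(y0)) {
    stop("x, m and y must each be non-constant", call. = FALSE)
  }
  theta_hat <- paths_core(x0, m0, y0, pd$Z, spec$robust, spec$tuning,
                          spec$max_iter, spec$tol)
  if (is.null(theta_hat)) stop("path model fit failed", call. = FALSE)

  B <- spec$n_boot
  n <- pd$n
  draws <- matrix(NA_real_, nrow = B, ncol = 5L)
  n_redrawn <- 0L
  scale_fun <- if (spec$fixed_scaling) {
    cx <- mean(pd$x); sx <- stats::sd(pd$x)
    cm <- mean(pd$m); sm <- stats::sd(pd$m)
    cy <- mean(pd$y); sy <- stats::sd(pd$y)
    function(idx) {
      list(x = (pd$x[idx] - cx) / sx, m = (pd$m[idx] - cm) / sm,
           y = (pd$y[idx] - cy) / sy)
    }
  } else {
    function(idx) {
      list(x = zsc(pd$x[idx]), m = zsc(pd$m[idx]), y = zsc(pd$y[idx]))
    }
  }
  with_seed(spec$seed, {
    b <- 1L
    while (b <= B) {
      idx <- sample.int(n, n, replace = TRUE)
      sc <- scale_fun(idx)
      th <- NULL
      if (!is.null(sc$x) && !is.null(sc$m) && !is.null(sc$y)) {
        Zb <- pd$Z[idx, , drop = FALSE]
        th <- suppressWarnings(
          tryCatch(paths_core(sc$x, sc$m, sc$y, Zb, spec$robust,
                              spec$tuning, spec$max_iter, spec$tol),
                   error = function(e) NULL))
      }
      if (is.null(th) || anyNA(th)) {
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 0.1 * B) {
          stop("more than 10% of bootstrap resamples failed to fit",
               call. = FALSE)
        }
        next
      }
      draws[b, ] <- th
      b <- b + 1L
    }
  })

  dir_of <- function(est) if (est >= 0) 1 else -1
  dir_ab <- if (!is.null(spec$expected_sign_ab)) {
    if (spec$expected_sign_ab == "+") 1 else -1
  } else {
    dir_of(theta_hat["ab"])
  }
  pvals <- numeric(5)
  dirs <- c(dir_of(theta_hat["a"]), dir_of(theta_hat["b"]),
            dir_of(theta_hat["c"]), dir_of(theta_hat["c_prime"]), dir_ab)
  for (j in 1:5) {
    pvals[j] <- bc_pvalue(theta_hat[j], draws[, j], dirs[j], spec$tails)
  }
  ci <- bc_interval(theta_hat["ab"], draws[, 5], level = 1 - spec$alpha)

  structure(list(
    beta_a = unname(theta_hat["a"]),
    beta_b = unname(theta_hat["b"]),
    beta_c = unname(theta_hat["c"]),
    beta_c_prime = unname(theta_hat["c_prime"]),
    beta_ab = unname(theta_hat["ab"]),
    p_a = pvals[1], p_b = pvals[2], p_c = pvals[3],
    p_c_prime = pvals[4], p_ab = pvals[5],
    n_used = n, n_boot_effective = B, n_redrawn = n_redrawn,
    boot_mean_ab = mean(draws[, 5]), boot_sd_ab = stats::sd(draws[, 5]),
    ab_ci_lower = unname(ci["lower"]), ab_ci_upper = unname(ci["upper"]),
    alpha = spec$alpha, tails = spec$tails, robust = spec$robust,
    seed = spec$seed), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation path model (", if (x$robust) "robust IRLS" else "OLS",
      ", ", x$n_boot_effective, " bootstrap resamples, ", x$tails,
      "-tailed)\n", sep = "")
  paths <- c(a = x$beta_a, b = x$beta_b, c = x$beta_c,
             "c'" = x$beta_c_prime, ab = x$beta_ab)
  ps <- c(x$p_a, x$p_b, x$p_c, x$p_c_prime, x$p_ab)
  for (i in seq_along(paths)) {
    cat(sprintf("  %-3s beta = %8.4f  p = %.4f\n", names(paths)[i],
                paths[i], ps[i]))
  }
  cat(sprintf("  ab %.0f%% CI [%.4f, %.4f], n = %d\n",
              100 * (1 - x$alpha), x$ab_ci_lower, x$ab_ci_upper, x$n_used))
  invisible(x)
}
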