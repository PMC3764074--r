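# Parameter bootstrap measurement-error correction and SIMEX refinement.
#
# The bootstrap re-simulates the whole two-stage data-generating process from
# the fitted models: new monitor observations and subject outcomes from the
# exposure and health fits (Berkson-like error: the re-predicted surface is
# still smoothed), and, for lambda > 0, new exposure-model parameters from
# their estimated sampling density scaled by lambda (classical-like error).

#' Bootstrap configuration
#'
#' @param B Number of bootstrap replicates (>= 2). The reference analysis in
#'   this field uses B = 30,000; the desk-scale default here is 1,000 and
#'   Monte-Carlo error is reported alongside every bootstrap quantity.
#' @param lambda Scaling of the parameter sampling density (>= 0); 1 is the
#'   full parameter bootstrap, 0 the partial parametric bootstrap.
#' @param seed Root seed; each replicate derives its own stream from it, and
#'   runs at different lambda share those streams (common random numbers).
#' @param lambda_grid Sorted grid containing 0, for SIMEX.
#' @param extrapolant Polynomial degree of the SIMEX extrapolation fit.
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 1000, lambda = 1, seed = 1L,
                             lambda_grid = c(0, 0.5, 1, 1.5, 2),
                             extrapolant = 2) {
  if (B < 2) abort("B must be >= 2.")
  if (lambda < 0) abort("lambda must be >= 0.")
  lambda_grid <- sort(unique(lambda_grid))
  if (!0 %in% lambda_grid) abort("lambda_grid must contain 0.")
  structure(list(B = as.integer(B), lambda = lambda, seed = as.integer(seed),
    lambda_grid = lambda_grid, extrapolant = as.integer(extrapolant)),
    class = "bootstrap_config")
}

#' Sampling density of the exposure-model parameters
#'
#' Multivariate normal for `(alpha, log theta)` centered at the estimates
#' with the inverse-observed-information covariance stored in the kriging
#' fit. Parameter draws back-transform `theta` from the log scale, so
#' nugget/partial sill/range are positive by construction.
#'
#' @param kf A [fit_universal_kriging()] fit with `param_cov`.
#' @return List with `mean`, `cov`, and the Cholesky factor `chol_cov`.
#' @export
sampling_density <- function(kf) {
  stopifnot(inherits(kf, "kriging_fit"))
  if (is.null(kf$param_cov) || anyNA(kf$param_cov)) {
    abort("Kriging fit has no usable parameter covariance; refit with hessian = TRUE.")
  }
  V <- kf$param_cov
  V2 <- nearest_psd(V)
  if (max(abs(V2 - V)) > 1e-10 * max(1, max(abs(V)))) {
    warn("Parameter covariance projected to the nearest PSD matrix.")
  }
  # numerical guard: when a variance component sits at its boundary the
  # observed information is degenerate and the log-scale variance explodes;
  # cap log-theta SDs at 5 (a factor ~150 each way, far beyond any
  # informative fit) so draws stay computable
  n_par <- nrow(V2)
  idx_theta <- (n_par - 2):n_par
  capped <- FALSE
  for (i in idx_theta) {
    if (V2[i, i] > 25) {
      f <- sqrt(25 / V2[i, i])
      V2[i, ] <- V2[i, ] * f
      V2[, i] <- V2[, i] * f
      capped <- TRUE
    }
  }
  if (capped) {
    warn("Degenerate parameter covariance: log-scale SDs capped at 5.")
    V2 <- nearest_psd(V2)
  }
  m <- c(kf$alpha, kf$log_theta)
  U <- chol(V2 + diag(1e-12 * max(max(diag(V2)), 1e-12), nrow(V2)))
  list(mean = m, cov = V2, chol_cov = U,
    theta_hat = kf$theta)
}

# One parameter draw: mean + sqrt(lambda) * t(U) z, split into alpha / theta.
# Drawn theta is clamped to a wide window around the point estimate (variance
# components within 50x the total variance, range within a factor 50); the
# clamp never binds for well-identified fits.
draw_params <- function(dens, lambda, z, n_alpha) {
  par <- dens$mean + sqrt(lambda) * as.numeric(crossprod(dens$chol_cov, z))
  th <- exp(par[n_alpha + 1:3])
  tot <- dens$theta_hat[["tau2"]] + dens$theta_hat[["sigma2"]]
  th[1] <- min(th[1], 50 * tot)
  th[2] <- min(th[2], 50 * tot)
  th[3] <- min(max(th[3], dens$theta_hat[["phi"]] / 50), 50 * dens$theta_hat[["phi"]])
  list(alpha = par[seq_len(n_alpha)], theta = th)
}

# Precompute everything replicate loops need.
pb_setup <- function(study, efit, hfit) {
  kf <- efit$kriging
  Xo <- design_matrix(kf$scores_obs)
  Xs <- design_matrix(efit$scores_subjects)
  nm <- nrow(Xo); ns <- nrow(Xs)
  coords_all <- rbind(kf$coords_obs, efit$coords_subjects)
  mu_all <- c(Xo %*% kf$alpha, Xs %*% kf$alpha)
  th <- kf$theta
  U_all <- if (th[["sigma2"]] == 0) NULL else
    chol_jitter(cov_matrix(th, dist_matrix(coords_all), kf$family))
  D_oo <- dist_matrix(kf$coords_obs)
  D_so <- dist_matrix(efit$coords_subjects, kf$coords_obs)
  Z <- if (length(hfit$z_names) > 0) {
    as.matrix(study$subjects[, hfit$z_names, drop = FALSE])
  } else {
    matrix(0, ns, 0)
  }
  # fixed-parameter (lambda = 0) prediction operator, reused every replicate
  S0 <- cov_matrix(th, D_oo, kf$family)
  U0 <- chol_jitter(S0)
  C0 <- cross_cov(th, D_so, kf$family)
  K0 <- t(backsolve(U0, backsolve(U0, t(C0), transpose = TRUE)))
  list(kf = kf, Xo = Xo, Xs = Xs, nm = nm, ns = ns, mu_all = mu_all,
    U_all = U_all, D_oo = D_oo, D_so = D_so, Z = Z, K0 = K0,
    beta = c(hfit$beta0, hfit$beta_x, hfit$beta_z),
    sigma_resid = hfit$sigma_resid,
    dens = sampling_density(kf))
}

# Draw one replicate's simulated data from precomputed pieces.
sim_rep <- function(st, seed_j) {
  n_all <- st$nm + st$ns
  n_par <- length(st$dens$mean)
  withr::with_seed(seed_j, {
    z_all <- rnorm(n_all)
    eps <- rnorm(st$ns)
    z_par <- rnorm(n_par)
  })
  x_all <- if (is.null(st$U_all)) {
    st$mu_all + sqrt(st$kf$theta[["tau2"]]) * z_all
  } else {
    st$mu_all + as.numeric(crossprod(st$U_all, z_all))
  }
  x_mon <- x_all[seq_len(st$nm)]
  x_sub <- x_all[-seq_len(st$nm)]
  W_true <- x_sub^2
  mu_y <- st$beta[1] + W_true * st$beta[2]
  if (ncol(st$Z) > 0) mu_y <- mu_y + as.numeric(st$Z %*% st$beta[-(1:2)])
  list(x_mon = x_mon, x_sub = x_sub,
    y = mu_y + st$sigma_resid * eps, z_par = z_par)
}

# Re-predict subject exposure with given (alpha, theta) applied to the
# simulated monitor data, then refit the health OLS; returns beta_x.
rep_beta <- function(st, rep, alpha, theta, fixed = FALSE) {
  if (fixed) {
    pred <- as.numeric(st$Xs %*% alpha) +
      as.numeric(st$K0 %*% (rep$x_mon - st$Xo %*% alpha))
  } else {
    S <- cov_matrix(theta, st$D_oo, st$kf$family)
    U <- chol_jitter(S)
    r <- rep$x_mon - as.numeric(st$Xo %*% alpha)
    w <- backsolve(U, backsolve(U, r, transpose = TRUE))
    C <- cross_cov(theta, st$D_so, st$kf$family)
    pred <- as.numeric(st$Xs %*% alpha) + as.numeric(C %*% w)
  }
  W <- pmax(pred, 0)^2
  fit <- lm.fit(cbind(1, W, st$Z), rep$y)
  unname(fit$coefficients[2])
}

# Shared engine: B replicates, beta_x draws at every lambda in `lambdas`
# using common random numbers. Returns B x length(lambdas) matrix (NA rows
# for dropped replicates) plus drop count.
pb_run <- function(study, efit, hfit, B, lambdas, seed) {
  st <- pb_setup(study, efit, hfit)
  n_alpha <- length(st$kf$alpha)
  draws <- matrix(NA_real_, B, length(lambdas))
  n_drop <- 0L
  for (j in seq_len(B)) {
    res <- tryCatch({
      rep <- sim_rep(st, child_seed(seed, 1000 + j))
      vapply(lambdas, function(l) {
        if (l == 0) {
          rep_beta(st, rep, st$kf$alpha, st$kf$theta, fixed = TRUE)
        } else {
          p <- draw_params(st$dens, l, rep$z_par, n_alpha)
          rep_beta(st, rep, p$alpha, p$theta)
        }
      }, numeric(1))
    }, error = function(e) NULL)
    if (is.null(res)) n_drop <- n_drop + 1L else draws[j, ] <- res
  }
  if (n_drop > 0.05 * B) {
    abort(sprintf("Parameter bootstrap aborted: %d of %d replicates failed.", n_drop, B))
  }
  if (n_drop > 0) inform(sprintf("%d bootstrap replicate(s) dropped.", n_drop))
  list(draws = draws[stats::complete.cases(draws), , drop = FALSE], n_drop = n_drop)
}

#' Parameter bootstrap for measurement-error correction
#'
#' Runs the parameter bootstrap: for each replicate, (a) new monitor
#' observations and true subject exposures are drawn jointly from the fitted
#' exposure model and health outcomes from the fitted health model; (b) new
#' exposure-model parameters are drawn from their sampling density with
#' covariance scaled by `lambda`; (c) subject exposures are re-predicted by
#' universal kriging with the drawn parameters applied to the simulated
#' monitor data; (d) the health OLS is refit, yielding one replicate
#' `beta_x_j`. The bias is the mean of the `lambda` draws minus the mean of
#' a `lambda = 0` run sharing the same replicate random-number streams; the
#' bootstrap SE is the sample SD of the draws.
#'
#' @param study The study the fits came from (provides the adjustment
#'   covariates and subject geometry).
#' @param efit A [fit_exposure()] fit (with parameter covariance).
#' @param hfit The naive [fit_health_ols()] fit.
#' @param cfg A [bootstrap_config()].
#' @return Object of class `bootstrap_result`: `beta_draws`, `mean_lambda`,
#'   `bias`, `beta_corrected`, `se_boot`, `mc_se`, `lambda`, `B`, `n_drop`,
#'   plus the matched `lambda = 0` summaries.
#' @export
parameter_bootstrap <- function(study, efit, hfit, cfg = bootstrap_config()) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  lambdas <- unique(c(0, cfg$lambda))
  run <- pb_run(study, efit, hfit, cfg$B, lambdas, cfg$seed)
  d0 <- run$draws[, 1]
  dl <- run$draws[, ncol(run$draws)]
  bias <- mean(dl) - mean(d0)
  se <- sd(dl)
  structure(list(
    beta_draws = dl,
    beta_draws_lambda0 = d0,
    mean_lambda = mean(dl),
    mean_lambda0 = mean(d0),
    bias = bias,
    beta_naive = hfit$beta_x,
    beta_corrected = hfit$beta_x - bias,
    se_boot = se,
    se_boot_lambda0 = sd(d0),
    mc_se = se / sqrt(2 * (length(dl) - 1)),
    lambda = cfg$lambda, B = cfg$B, n_drop = run$n_drop, seed = cfg$seed
  ), class = "bootstrap_result")
}

#' Partial parametric bootstrap (lambda = 0)
#'
#' Specialization of [parameter_bootstrap()] with the exposure-model
#' parameters held fixed: only the Berkson-like error from smoothing the
#' exposure surface is propagated, and the bias is exactly zero by
#' construction.
#'
#' @inheritParams parameter_bootstrap
#' @export
partial_parametric_bootstrap <- function(study, efit, hfit, cfg = bootstrap_config()) {
  cfg$lambda <- 0
  parameter_bootstrap(study, efit, hfit, cfg)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Parameter bootstrap (B = %d, lambda = %g, %d dropped)\n",
    x$B, x$lambda, x$n_drop))
  cat(sprintf("  naive beta_x      = %.5g\n", x$beta_naive))
  cat(sprintf("  bias (classical)  = %.5g\n", x$bias))
  cat(sprintf("  corrected beta_x  = %.5g\n", x$beta_corrected))
  cat(sprintf("  bootstrap SE      = %.5g  (MC error %.2g)\n", x$se_boot, x$mc_se))
  invisible(x)
}

#' @export
tidy.bootstrap_result <- function(x, ...) {
  ci <- normal_ci(x$beta_corrected, x$se_boot)
  tibble(term = "w", estimate = x$beta_corrected, std.error = x$se_boot,
    conf.low = ci[, 1], conf.high = ci[, 2],
    lambda = x$lambda, bias = x$bias, B = x$B)
}

#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble(B = x$B, lambda = x$lambda, se_boot = x$se_boot,
    se_boot_lambda0 = x$se_boot_lambda0, bias = x$bias, mc_se = x$mc_se,
    n_drop = x$n_drop)
}

#' Simulate one bootstrap study replicate
#'
#' Exposes step (a) of the parameter bootstrap: a joint draw of monitor
#' observations and true subject exposures from the fitted exposure model
#' (point estimates), and health outcomes from the fitted health model with
#' residual-SD noise.
#'
#' @inheritParams parameter_bootstrap
#' @param seed Seed for this replicate.
#' @return List with `monitor_obs` (sqrt scale), `true_sqrt_subjects`,
#'   `outcomes`.
#' @export
simulate_study_replicate <- function(study, efit, hfit, seed = 1L) {
  st <- pb_setup(study, efit, hfit)
  rep <- sim_rep(st, seed)
  list(monitor_obs = rep$x_mon, true_sqrt_subjects = rep$x_sub, outcomes = rep$y)
}

#' SIMEX refinement of the bootstrap bias estimate
#'
#' Computes the classical-error bias on a grid of `lambda` values with
#' shared replicate streams, fits a polynomial trend in `lambda`, and reports
#' the fitted bias at `lambda = 1` together with the corrected estimate.
#'
#' @inheritParams parameter_bootstrap
#' @param at Lambda value at which the fitted bias is evaluated (default 1).
#' @return Object of class `simex_result`: per-lambda tibble, the polynomial
#'   coefficients, `bias_at`, `beta_corrected`.
#' @export
simex_bias <- function(study, efit, hfit, cfg = bootstrap_config(), at = 1) {
  grid <- cfg$lambda_grid
  if (length(grid) < 3) abort("lambda_grid needs at least 3 values.")
  if (cfg$extrapolant >= length(grid)) {
    abort("Extrapolant degree must be smaller than the grid size.")
  }
  run <- pb_run(study, efit, hfit, cfg$B, grid, cfg$seed)
  means <- colMeans(run$draws)
  bias <- means - means[grid == 0]
  fit <- simex_extrapolate(grid, bias, cfg$extrapolant, at = at)
  structure(list(
    table = tibble(lambda = grid, mean_beta = means, bias = bias,
      se = apply(run$draws, 2, sd)),
    coef = fit$coef,
    bias_at = fit$value, at = at,
    beta_naive = hfit$beta_x,
    beta_corrected = hfit$beta_x - fit$value,
    B = cfg$B, n_drop = run$n_drop
  ), class = "simex_result")
}

#' Polynomial extrapolation used by SIMEX
#'
#' Fits `bias ~ poly(lambda, degree)` by least squares and evaluates the
#' fitted curve at `at`.
#'
#' @param lambda,bias Equal-length numeric vectors.
#' @param degree Polynomial degree (must be < number of distinct lambdas).
#' @param at Evaluation point.
#' @return List with `coef` and fitted `value` at `at`.
#' @export
simex_extrapolate <- function(lambda, bias, degree = 2, at = 1) {
  if (degree >= length(unique(lambda))) {
    abort("Extrapolant degree must be smaller than the number of grid points.")
  }
  X <- outer(lambda, 0:degree, "^")
  cf <- qr.coef(qr(X), bias)
  cf[is.na(cf)] <- 0
  list(coef = cf, value = sum(cf * at^(0:degree)))
}

#' @export
print.simex_result <- function(x, ...) {
  cat(sprintf("SIMEX bias extrapolation (B = %d per lambda)\n", x$B))
  print(x$table)
  cat(sprintf("  fitted bias at lambda = %g: %.5g\n", x$at, x$bias_at))
  cat(sprintf("  corrected beta_x: %.5g\n", x$beta_corrected))
  invisible(x)
}

#' @export
tidy.simex_result <- function(x, ...) x$table
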