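# Shared small setup: fitted two-stage models on a compact study.
me_setup <- function(seed = 61, theta = c(0.0074, 0.0025, 413)) {
  st <- simulate_study(scenario_config(n_monitors = 60, n_subjects = 80,
    p_covariates = 12, n_distance = 2, theta_true = theta, seed = seed))
  ef <- fit_exposure(st, k = 2)
  pred <- predict_subjects(ef)
  z <- st$subjects[grep("^z_", names(st$subjects))]
  hf <- fit_health_ols(st$subjects$y_outcome, pred$pred_raw, z)
  list(st = st, ef = ef, hf = hf)
}

test_that("bootstrap configuration is validated", {
  expect_error(bootstrap_config(B = 1), "B must")
  expect_error(bootstrap_config(lambda = -0.5), "lambda")
  expect_error(bootstrap_config(lambda_grid = c(0.5, 1)), "contain 0")
  cfg <- bootstrap_config(lambda_grid = c(1, 0, 0.5))
  expect_equal(cfg$lambda_grid, c(0, 0.5, 1))
})

test_that("the sampling density scales with lambda and keeps theta positive", {
  s <- me_setup()
  dens <- sampling_density(s$ef$kriging)
  n_par <- length(dens$mean)
  n_alpha <- length(s$ef$kriging$alpha)
  withr::with_seed(1, Zs <- matrix(rnorm(5000 * n_par), 5000, n_par))
  for (lam in c(0.5, 1)) {
    draws <- t(apply(Zs, 1, function(z) {
      p <- plskrige:::draw_params(dens, lam, z, n_alpha)
      c(p$alpha, log(p$theta))
    }))
    emp <- cov(draws)
    expect_lt(max(abs(emp - lam * dens$cov)) / max(abs(dens$cov)), 0.15 * lam + 1e-12)
    th <- exp(draws[, n_par - 2:0])
    expect_true(all(th > 0))
  }
  # lambda = 0: every draw is the point estimate
  p0 <- plskrige:::draw_params(dens, 0, rnorm(n_par), n_alpha)
  expect_equal(unname(p0$alpha), unname(s$ef$kriging$alpha), tolerance = 1e-12)
  expect_equal(unname(p0$theta), unname(s$ef$kriging$theta), tolerance = 1e-12)
})

test_that("study replicates have the fitted model's moments", {
  s <- me_setup()
  kf <- s$ef$kriging
  reps <- lapply(1:200, function(j) simulate_study_replicate(s$st, s$ef, s$hf,
    seed = 9000 + j))
  xm <- sapply(reps, function(r) r$monitor_obs)
  # per-site variance matches the sill
  sill <- sum(kf$theta[c("tau2", "sigma2")])
  expect_equal(mean(apply(xm, 1, var)), sill, tolerance = 0.25)
  # outcomes are deterministic given exposures when sigma_resid = 0
  s0 <- s
  s0$hf$sigma_resid <- 0
  r1 <- simulate_study_replicate(s0$st, s0$ef, s0$hf, seed = 1)
  r2 <- simulate_study_replicate(s0$st, s0$ef, s0$hf, seed = 1)
  expect_identical(r1$outcomes, r2$outcomes)
  b <- c(s0$hf$beta0, s0$hf$beta_x, s0$hf$beta_z)
  Z <- as.matrix(s0$st$subjects[grep("^z_", names(s0$st$subjects))])
  expect_equal(r1$outcomes,
    b[1] + r1$true_sqrt_subjects^2 * b[2] + as.numeric(Z %*% b[-(1:2)]),
    tolerance = 1e-12)
})

test_that("a nugget-only fit simulates uncorrelated exposure residuals", {
  s <- me_setup()
  kf <- s$ef$kriging
  kf$theta <- c(tau2 = 0.008, sigma2 = 0, phi = 400)
  s$ef$kriging <- kf
  mu <- as.numeric(cbind(1, kf$scores_obs) %*% kf$alpha)
  xm <- sapply(1:300, function(j)
    simulate_study_replicate(s$st, s$ef, s$hf, seed = 200 + j)$monitor_obs - mu)
  D <- plskrige:::dist_matrix(kf$coords_obs)
  diag(D) <- Inf
  pair <- which(D == min(D), arr.ind = TRUE)[1, ]
  expect_lt(abs(cor(xm[pair[1], ], xm[pair[2], ])), 0.2)
})

test_that("the bootstrap is reproducible and honors the shared-seed contract", {
  s <- me_setup()
  cfg <- bootstrap_config(B = 40, lambda = 1, seed = 5)
  pb1 <- parameter_bootstrap(s$st, s$ef, s$hf, cfg)
  pb2 <- parameter_bootstrap(s$st, s$ef, s$hf, cfg)
  expect_identical(pb1$beta_draws, pb2$beta_draws)
  expect_identical(pb1$bias, pb2$bias)
  # the lambda = 0 companion stream is the partial parametric bootstrap
  pp <- partial_parametric_bootstrap(s$st, s$ef, s$hf, cfg)
  expect_identical(pp$beta_draws, pb1$beta_draws_lambda0)
  expect_identical(pp$bias, 0)
  expect_identical(pp$beta_corrected, s$hf$beta_x)
  # invariant: corrected = naive - bias; SE is the draw SD
  expect_equal(pb1$beta_corrected, s$hf$beta_x - pb1$bias)
  expect_equal(pb1$se_boot, sd(pb1$beta_draws))
})

test_that("lambda = 0 and lambda = 1 SEs are ordered up to MC noise", {
  s <- me_setup()
  pb <- parameter_bootstrap(s$st, s$ef, s$hf, bootstrap_config(B = 150, seed = 6))
  expect_lte(pb$se_boot_lambda0, pb$se_boot + 2 * pb$mc_se)
})

test_that("SIMEX extrapolation recovers exact polynomial bias curves", {
  lam <- c(0, 0.5, 1, 1.5, 2)
  bias_lin <- 0.013 * lam
  fit <- simex_extrapolate(lam, bias_lin, degree = 2, at = 1)
  expect_equal(fit$value, 0.013, tolerance = 1e-6)
  expect_equal(unname(fit$coef[2]), 0.013, tolerance = 1e-6)
  expect_equal(unname(fit$coef[3]), 0, tolerance = 1e-8)
  bias_quad <- 0.01 * lam - 0.004 * lam^2
  fit2 <- simex_extrapolate(lam, bias_quad, degree = 2, at = 2)
  expect_equal(fit2$value, 0.01 * 2 - 0.004 * 4, tolerance = 1e-10)
  expect_error(simex_extrapolate(c(0, 1), c(0, 1), degree = 2), "degree")
})

test_that("SIMEX agrees with the directly computed bias on a shared grid", {
  s <- me_setup()
  cfg <- bootstrap_config(B = 120, seed = 8, lambda_grid = c(0, 0.5, 1))
  sx <- simex_bias(s$st, s$ef, s$hf, cfg)
  expect_equal(sx$table$bias[1], 0)
  direct <- parameter_bootstrap(s$st, s$ef, s$hf,
    bootstrap_config(B = 120, seed = 8, lambda = 1))
  # same seed, same replicate streams: the lambda = 1 grid column must match
  expect_equal(sx$table$bias[sx$table$lambda == 1],
    direct$bias, tolerance = 1e-12)
  # quadratic through 3 points passes through the lambda = 1 value
  expect_equal(sx$bias_at, direct$bias, tolerance = 1e-10)
  # small-bias regime: corrected estimate close to naive relative to SE
  expect_lt(abs(sx$beta_corrected - s$hf$beta_x), sx$table$se[3])
})
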