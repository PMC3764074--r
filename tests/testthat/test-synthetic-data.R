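test_that("scenario_config validates its inputs", {
  expect_error(scenario_config(region_size = 0), "region_size")
  expect_error(scenario_config(n_latent = 5, p_covariates = 3,
    alpha_true = rep(0.1, 6)), "n_latent")
  expect_error(scenario_config(theta_true = c(-1, 1, 10)), "theta")
  expect_error(scenario_config(alpha_true = c(1, 2)), "alpha_true")
  cfg <- scenario_config()
  expect_s3_class(cfg, "scenario_config")
  expect_true(all(cfg$theta_true[1:2] >= 0) && cfg$theta_true[3] > 0)
})

test_that("generated locations respect the region and the cluster rule", {
  cfg <- scenario_config(n_monitors = 288, n_subjects = 500, seed = 1)
  loc <- generate_locations(cfg)
  expect_equal(nrow(loc$monitors), 288)
  expect_equal(nrow(loc$subjects), 500)
  all_xy <- c(loc$monitors$x, loc$monitors$y, loc$subjects$x, loc$subjects$y)
  expect_true(all(all_xy >= 0 & all_xy <= cfg$region_size))

  # degenerate case: everyone clustered
  cfg1 <- scenario_config(cluster_fraction = 1, n_subjects = 200, seed = 2)
  loc1 <- generate_locations(cfg1)
  d_min <- apply(
    plskrige:::dist_matrix(cbind(loc1$subjects$x, loc1$subjects$y),
      loc1$cluster_centers), 1, min)
  expect_true(all(d_min < 6 * cfg1$cluster_sd))
})

test_that("generators are pure functions of the configuration", {
  cfg <- scenario_config(n_monitors = 40, n_subjects = 30, p_covariates = 8,
    seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$monitors, s2$monitors)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$covariates_subjects, s2$covariates_subjects)
})

test_that("covariate table has the advertised low-rank structure", {
  cfg <- scenario_config(n_monitors = 400, n_subjects = 1, p_covariates = 50,
    n_latent = 2, n_distance = 0, cov_noise_sd = 0.3, seed = 5)
  loc <- generate_locations(cfg)
  gc <- generate_covariates(loc$monitors[c("x", "y")], cfg)
  ev <- eigen(cov(as.matrix(gc$covariates)), symmetric = TRUE)$values
  # two dominant eigenvalues, then a noise floor
  expect_gt(ev[2], 5 * ev[3])

  # noiseless table has rank <= n_latent
  cfg0 <- scenario_config(n_monitors = 60, n_subjects = 1, p_covariates = 20,
    n_latent = 2, n_distance = 0, cov_noise_sd = 0, seed = 5)
  gc0 <- generate_covariates(generate_locations(cfg0)$monitors[c("x", "y")], cfg0)
  sv <- svd(scale(as.matrix(gc0$covariates), scale = FALSE))$d
  expect_lt(sv[3] / sv[1], 1e-8)

  # distance-type columns are positive
  gcd <- generate_covariates(loc$monitors[c("x", "y")],
    scenario_config(n_monitors = 400, n_subjects = 1, seed = 5))
  dist_cols <- grep("^dist", names(gcd$covariates), value = TRUE)
  expect_true(length(dist_cols) > 0)
  expect_true(all(as.matrix(gcd$covariates[dist_cols]) > 0))
})

test_that("true surface honors the noiseless and nugget-only limits", {
  cfg <- scenario_config(n_monitors = 50, n_subjects = 1,
    theta_true = c(0, 0, 100), alpha_true = c(1, 0.2, 0.1), seed = 3)
  loc <- generate_locations(cfg)
  gc <- generate_covariates(loc$monitors[c("x", "y")], cfg)
  x <- generate_true_surface(loc$monitors[c("x", "y")], gc$factors, cfg)
  expect_equal(x, as.numeric(cbind(1, gc$factors) %*% cfg$alpha_true),
    tolerance = 1e-12)

  # pure nugget: residuals at the two nearest sites are uncorrelated
  cfg_n <- scenario_config(n_monitors = 30, n_subjects = 1,
    theta_true = c(1, 0, 100), seed = 3)
  loc_n <- generate_locations(cfg_n)
  gc_n <- generate_covariates(loc_n$monitors[c("x", "y")], cfg_n)
  mu <- as.numeric(cbind(1, gc_n$factors) %*% cfg_n$alpha_true)
  D <- plskrige:::dist_matrix(as.matrix(loc_n$monitors[c("x", "y")]))
  diag(D) <- Inf
  pair <- which(D == min(D), arr.ind = TRUE)[1, ]
  resid <- replicate(200, {
    x <- generate_true_surface(loc_n$monitors[c("x", "y")], gc_n$factors,
      cfg_n, seed = sample.int(1e6, 1))
    (x - mu)[pair]
  })
  expect_lt(abs(cor(resid[1, ], resid[2, ])), 0.2)
})

test_that("field marginal variance matches the sill", {
  cfg <- scenario_s_like(n_monitors = 40, n_subjects = 1, seed = 9)
  loc <- generate_locations(cfg)
  gc <- generate_covariates(loc$monitors[c("x", "y")], cfg)
  mu <- as.numeric(cbind(1, gc$factors) %*% cfg$alpha_true)
  withr::with_seed(11, seeds <- sample.int(1e6, 300))
  draws <- sapply(seeds, function(s)
    generate_true_surface(loc$monitors[c("x", "y")], gc$factors, cfg, seed = s) - mu)
  v_site <- apply(draws, 1, var)
  sill <- sum(cfg$theta_true[1:2])
  expect_equal(mean(v_site), sill, tolerance = 0.15)
})

test_that("empirical semivariogram of a generated field matches gamma(d)", {
  theta <- c(0.3, 1, 400)
  cfg <- scenario_config(n_monitors = 120, n_subjects = 1, region_size = 2000,
    theta_true = theta, alpha_true = c(0, 0, 0), seed = 13)
  loc <- generate_locations(cfg)
  gc <- generate_covariates(loc$monitors[c("x", "y")], cfg)
  withr::with_seed(14, seeds <- sample.int(1e6, 150))
  D <- plskrige:::dist_matrix(as.matrix(loc$monitors[c("x", "y")]))
  iu <- upper.tri(D)
  gsum <- 0
  for (s in seeds) {
    x <- generate_true_surface(loc$monitors[c("x", "y")], gc$factors, cfg, seed = s)
    gsum <- gsum + 0.5 * (outer(x, x, "-")[iu])^2
  }
  gbar <- gsum / length(seeds)
  gtheo <- semivariogram("exponential", theta, D[iu])
  bins <- cut(D[iu], quantile(D[iu], seq(0, 1, 0.1)), include.lowest = TRUE)
  emp <- tapply(gbar, bins, mean)
  theo <- tapply(gtheo, bins, mean)
  expect_equal(as.numeric(emp), as.numeric(theo), tolerance = 0.12)
})

test_that("health outcomes follow the linear model in the exact limits", {
  cfg <- scenario_config(n_monitors = 5, n_subjects = 100, sigma_y = 0,
    beta_true = c(0.7, 0), seed = 2)
  y <- generate_health(rep(1.2, 100), matrix(0, 100, 0), cfg)
  expect_equal(y, rep(0.7, 100), tolerance = 1e-12)

  # noiseless OLS recovers beta exactly
  cfg2 <- scenario_config(n_monitors = 5, n_subjects = 150, sigma_y = 0,
    beta_true = c(0.7, 0.055, 0.3, -0.2), seed = 4)
  withr::with_seed(5, {
    xs <- runif(150, 0.5, 1.5)
    Z <- matrix(rnorm(300), 150, 2)
  })
  y2 <- generate_health(xs, Z, cfg2)
  b <- coef(lm(y2 ~ I(xs^2) + Z))
  expect_equal(unname(b), c(0.7, 0.055, 0.3, -0.2), tolerance = 1e-9)
  expect_error(generate_health(xs, matrix(0, 10, 2), cfg2), "row-aligned")
})

test_that("OLS on true exposures is unbiased at the published effect size", {
  # mean beta_x-hat over replicate studies within 2 MC-SEs of the truth
  beta_hat <- sapply(1:50, function(r) {
    cfg <- scenario_config(n_monitors = 5, n_subjects = 2000, sigma_y = 0.19,
      beta_true = c(0.68, 0.055, 0.02, -0.01), seed = 6000 + r)
    withr::with_seed(cfg$seed, {
      xs <- runif(2000, 0.6, 1.2)
      Z <- matrix(rnorm(4000), 2000, 2)
    })
    y <- generate_health(xs, Z, cfg)
    coef(lm(y ~ I(xs^2) + Z))[2]
  })
  mc_se <- sd(beta_hat) / sqrt(length(beta_hat))
  expect_lt(abs(mean(beta_hat) - 0.055), 2 * mc_se)
})
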