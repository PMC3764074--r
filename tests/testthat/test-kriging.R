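test_that("semivariogram families have the documented closed forms", {
  th <- c(0.2, 1, 50)
  expect_equal(semivariogram("spherical", th, 50), 1.2)         # sill at range
  expect_equal(semivariogram("spherical", th, 500), 1.2)
  expect_equal(semivariogram("exponential", th, 50), 0.2 + 1 * (1 - exp(-1)))
  expect_equal(semivariogram("cubic", th, 50), 1.2)
  # origin behavior: gamma(0) = 0, limit from above is the nugget
  for (fam in c("exponential", "spherical", "cubic")) {
    expect_equal(semivariogram(fam, th, 0), 0)
    expect_equal(semivariogram(fam, th, 1e-9), 0.2, tolerance = 1e-6)
  }
  # published S parameters, exponential form at d = phi
  expect_equal(semivariogram("exponential", c(0.0007, 0.0251, 2145), 2145),
    0.0007 + 0.0251 * (1 - exp(-1)))
  expect_error(semivariogram("gaussianish", th, 1), "family")
  expect_error(semivariogram("exponential", c(-1, 1, 1), 1), "theta")
})

test_that("profile likelihood reduces to iid OLS when sigma2 = 0", {
  f <- sim_field(40, c(0.5, 0, 100), seed = 10)
  tau2 <- 0.37
  nll <- profile_negloglik(c(tau2, 0, 123), f$scores, f$x, f$coords)
  ols <- lm.fit(cbind(1, f$scores), f$x)
  r <- ols$residuals
  nll_direct <- 0.5 * (length(r) * log(2 * pi * tau2) + sum(r^2) / tau2)
  expect_equal(nll, nll_direct, tolerance = 1e-10)
})

test_that("profiled alpha equals the full-likelihood minimum over alpha", {
  f <- sim_field(25, c(0.2, 0.8, 400), seed = 11)
  theta <- c(0.3, 0.7, 350)
  prof <- plskrige:::profile_negloglik_D(theta, cbind(1, f$scores), f$x,
    plskrige:::dist_matrix(f$coords), "exponential", return_alpha = TRUE)
  S <- plskrige:::cov_matrix(theta, plskrige:::dist_matrix(f$coords), "exponential")
  full <- function(a) {
    r <- f$x - cbind(1, f$scores) %*% a
    0.5 * (length(r) * log(2 * pi) + determinant(S)$modulus[1] +
      drop(t(r) %*% solve(S, r)))
  }
  opt <- optim(rep(0, 3), full, method = "BFGS")
  expect_equal(prof$nll, opt$value, tolerance = 1e-6)
  expect_equal(prof$alpha, opt$par, tolerance = 1e-4)
})

test_that("profile likelihood is invariant to site order and mean shifts", {
  f <- sim_field(30, c(0.2, 0.8, 300), seed = 12)
  theta <- c(0.25, 0.7, 280)
  nll <- profile_negloglik(theta, f$scores, f$x, f$coords)
  perm <- sample(30)
  expect_equal(profile_negloglik(theta, f$scores[perm, ], f$x[perm],
    f$coords[perm, ]), nll, tolerance = 1e-9)
  expect_equal(profile_negloglik(theta, f$scores, f$x + 5, f$coords), nll,
    tolerance = 1e-8)
})

test_that("fitted theta is a local optimum on a surrounding grid", {
  f <- sim_field(50, c(0.3, 1, 400), seed = 13)
  kf <- fit_universal_kriging(f$scores, f$x, f$coords, hessian = FALSE)
  D <- plskrige:::dist_matrix(f$coords)
  X <- cbind(1, f$scores)
  v0 <- plskrige:::profile_negloglik_D(kf$theta, X, f$x, D, "exponential")
  for (d1 in c(-0.2, -0.1, 0, 0.1, 0.2)) {
    for (d2 in c(-0.2, -0.1, 0, 0.1, 0.2)) {
      for (d3 in c(-0.2, -0.1, 0, 0.1, 0.2)) {
        th <- kf$theta * exp(c(d1, d2, d3))
        expect_gte(plskrige:::profile_negloglik_D(th, X, f$x, D, "exponential"),
          v0 - 1e-6)
      }
    }
  }
})

test_that("universal kriging prediction equals the joint conditional mean", {
  for (r in 1:5) {
    f <- sim_field(30, c(0.2, 1, 350), seed = 20 + r)
    obs <- 1:22
    new <- 23:30
    kf <- fit_universal_kriging(f$scores[obs, ], f$x[obs], f$coords[obs, ],
      hessian = FALSE)
    pred <- predict_uk(kf, f$scores[new, ], f$coords[new, ])
    # oracle: conditional mean from the full joint covariance at theta-hat
    Dall <- plskrige:::dist_matrix(f$coords)
    C <- kf$theta[["sigma2"]] *
      corr_function("exponential", Dall, kf$theta[["phi"]])
    diag(C) <- diag(C) + kf$theta[["tau2"]]
    mu <- as.numeric(cbind(1, f$scores) %*% kf$alpha)
    cond <- mu[new] + (C[new, obs] - 0) %*%
      solve(C[obs, obs], f$x[obs] - mu[obs])
    # cross-covariance between distinct sites has no nugget term
    expect_equal(pred$pred_sqrt, as.numeric(cond), tolerance = 1e-8)
  }
})

test_that("kriging interpolates exactly at monitors when the nugget is zero", {
  f <- sim_field(25, c(0, 1, 300), seed = 33)
  kf <- fit_universal_kriging(f$scores, f$x, f$coords, hessian = FALSE)
  kf$theta[["tau2"]] <- 0
  pred <- predict_uk(kf, f$scores, f$coords)
  expect_equal(pred$pred_sqrt, f$x, tolerance = 1e-6)
})

test_that("predictions fall back to the regression mean in the limits", {
  f <- sim_field(30, c(0.3, 1, 300), seed = 34)
  kf <- fit_universal_kriging(f$scores, f$x, f$coords, hessian = FALSE)
  # no spatial component: prediction is T alpha
  kf0 <- kf
  kf0$theta[["sigma2"]] <- 0
  pred0 <- predict_uk(kf0, f$scores[1:5, ], f$coords[1:5, ] + 10)
  expect_equal(pred0$pred_sqrt,
    as.numeric(cbind(1, f$scores[1:5, ]) %*% kf$alpha), tolerance = 1e-12)
  # site far beyond the range: same limit
  far <- matrix(c(1e7, 1e7), 1, 2)
  predf <- predict_uk(kf, f$scores[1, , drop = FALSE], far)
  expect_equal(predf$pred_sqrt,
    drop(cbind(1, f$scores[1, , drop = FALSE]) %*% kf$alpha), tolerance = 1e-6)
})

test_that("adding a monitor never increases the kriging variance", {
  f <- sim_field(20, c(0.2, 1, 300), seed = 35)
  target_scores <- matrix(0, 1, 2)
  target_coords <- matrix(c(555, 444), 1, 2)
  kf_small <- fit_universal_kriging(f$scores[1:12, ], f$x[1:12], f$coords[1:12, ],
    hessian = FALSE)
  v_for <- function(obs_idx) {
    kf <- kf_small
    kf$scores_obs <- f$scores[obs_idx, , drop = FALSE]
    kf$conc_sqrt_obs <- f$x[obs_idx]
    kf$coords_obs <- f$coords[obs_idx, , drop = FALSE]
    predict_uk(kf, target_scores, target_coords, se = TRUE)$pred_var
  }
  for (m in 13:20) {
    expect_lte(v_for(c(1:12, m)), v_for(1:12) + 1e-10)
  }
})

test_that("duplicate monitor coordinates are rejected", {
  f <- sim_field(15, c(0.2, 1, 300), seed = 36)
  f$coords[2, ] <- f$coords[1, ]
  expect_error(fit_universal_kriging(f$scores, f$x, f$coords), "Duplicate")
})

test_that("nearest-monitor predictions use the closest, lowest-id monitor", {
  coords_obs <- rbind(c(0, 0), c(10, 0), c(0, 10))
  vals <- c(1, 2, 3)
  # coincident with monitor 2
  expect_equal(nearest_monitor(coords_obs, vals, rbind(c(10, 0)))$pred_sqrt, 2)
  # equidistant between monitors 2 and 3: lowest id wins
  expect_equal(nearest_monitor(coords_obs, vals, rbind(c(10, 10)))$pred_sqrt, 2)
  # id vector overrides row order for tie-breaking
  expect_equal(nearest_monitor(coords_obs, vals, rbind(c(10, 10)),
    ids_obs = c(9, 8, 7))$pred_sqrt, 3)
})
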