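#' Spatial correlation and semivariogram functions
#'
#' Isotropic correlation models used throughout the package. `d` is Euclidean
#' distance in km and `phi` the range parameter in km. The exponential model
#' decays as `exp(-d/phi)`; the spherical and cubic models reach zero
#' correlation (the full sill on the variogram scale) exactly at `d = phi`.
#'
#' @param family One of `"exponential"`, `"spherical"`, `"cubic"`.
#' @param d Non-negative distances (vector or matrix), km.
#' @param phi Range parameter, km (> 0).
#' @return Correlations in `[0, 1]`, same shape as `d`.
#' @export
corr_function <- function(family, d, phi) {
  if (any(d < 0)) abort("Distances must be non-negative.")
  if (phi <= 0) abort("Range parameter phi must be > 0.")
  h <- d / phi
  switch(family,
    exponential = exp(-h),
    spherical = ifelse(h < 1, 1 - 1.5 * h + 0.5 * h^3, 0),
    cubic = ifelse(h < 1,
      1 - (7 * h^2 - 8.75 * h^3 + 3.5 * h^5 - 0.75 * h^7), 0),
    abort(paste0("Unknown variogram family: ", family))
  )
}

#' @description
#' `semivariogram()` evaluates the corresponding semivariogram
#' `gamma(d) = tau2 + sigma2 * (1 - rho(d/phi))` for `d > 0`, with
#' `gamma(0) = 0` (the nugget is a discontinuity at the origin).
#'
#' @param theta Named or positional numeric vector `(tau2, sigma2, phi)`:
#'   nugget, partial sill, range.
#' @rdname corr_function
#' @export
semivariogram <- function(family, theta, d) {
  theta <- check_theta(theta)
  out <- theta[["tau2"]] + theta[["sigma2"]] *
    (1 - corr_function(family, d, theta[["phi"]]))
  out[d == 0] <- 0
  out
}

check_theta <- function(theta) {
  theta <- as.numeric(theta)
  if (length(theta) != 3L) abort("theta must be (tau2, sigma2, phi).")
  if (theta[1] < 0 || theta[2] < 0 || theta[3] <= 0) {
    abort("Invalid theta: need tau2 >= 0, sigma2 >= 0, phi > 0.")
  }
  c(tau2 = theta[1], sigma2 = theta[2], phi = theta[3])
}

# Residual covariance matrix Sigma(theta) = tau2 * I + sigma2 * rho(D/phi).
cov_matrix <- function(theta, D, family) {
  theta <- check_theta(theta)
  S <- theta[["sigma2"]] * corr_function(family, D, theta[["phi"]])
  diag(S) <- diag(S) + theta[["tau2"]]
  S
}

# Cross-covariance between prediction and observation sites: sigma2 * rho,
# no nugget (sites are distinct realizations of the smooth process).
cross_cov <- function(theta, D, family) {
  theta <- check_theta(theta)
  theta[["sigma2"]] * corr_function(family, D, theta[["phi"]])
}

#' Profile negative log-likelihood of the universal kriging model
#'
#' Gaussian negative log-likelihood of sqrt-scale concentrations with mean
#' `cbind(1, scores) %*% alpha` and covariance
#' `Sigma(theta) = tau2 * I + sigma2 * rho(d/phi)`, where the mean
#' coefficients `alpha` are profiled out by generalized least squares at the
#' supplied `theta`.
#'
#' @param theta `(tau2, sigma2, phi)` on the natural scale.
#' @param scores Matrix (or data frame) of PLS scores at monitor locations;
#'   an intercept column is added internally.
#' @param conc_sqrt Numeric vector of sqrt-scale observed concentrations.
#' @param coords Monitor coordinates (n x 2, km).
#' @param family Variogram family.
#' @return Scalar negative log-likelihood (smaller is better).
#' @export
profile_negloglik <- function(theta, scores, conc_sqrt, coords, family = "exponential") {
  D <- dist_matrix(as_coord_matrix(coords))
  profile_negloglik_D(theta, design_matrix(scores), conc_sqrt, D, family)
}

design_matrix <- function(scores) {
  if (is.null(scores)) return(matrix(1, 1, 1))
  X <- as.matrix(as_cov_matrix(scores))
  cbind(`(Intercept)` = 1, X)
}

# Distance-matrix variant used in fitting loops; also returns alpha_hat.
profile_negloglik_D <- function(theta, X, y, D, family, return_alpha = FALSE) {
  theta <- check_theta(theta)
  n <- length(y)
  S <- cov_matrix(theta, D, family)
  U <- tryCatch(chol(S), error = function(e) chol_jitter(S))
  # whitened GLS: solve triangular systems instead of forming Sigma^-1
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  qrX <- qr(Xw)
  alpha <- qr.coef(qrX, yw)
  r <- yw - Xw %*% alpha
  nll <- 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(U))) + sum(r^2))
  if (return_alpha) list(nll = as.numeric(nll), alpha = as.numeric(alpha)) else as.numeric(nll)
}

# Binned empirical semivariogram of residuals; used to seed the optimizer
# and for diagnostic plots.
empirical_variogram <- function(coords, resid, n_bins = 12, max_frac = 0.7) {
  D <- dist_matrix(as_coord_matrix(coords))
  iu <- upper.tri(D)
  d <- D[iu]
  g <- 0.5 * (outer(resid, resid, "-")[iu])^2
  keep <- d <= max_frac * max(d)
  d <- d[keep]; g <- g[keep]
  br <- seq(0, max(d), length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE)
  tibble(
    dist = tapply(d, bin, mean),
    gamma = tapply(g, bin, mean),
    n_pairs = as.integer(table(bin))
  ) %>% filter(!is.na(.data$dist), .data$n_pairs > 0)
}

#' Fit the universal kriging exposure model by profile maximum likelihood
#'
#' Numerically minimizes [profile_negloglik()] over `log(tau2)`, `log(sigma2)`,
#' `log(phi)` with a 3 x 3 x 3 multi-start grid seeded from the empirical
#' variogram of the OLS residuals (full Nelder-Mead runs are launched from the
#' best grid starts, then the best optimum is polished). The mean coefficients
#' `alpha` are recovered by GLS at the optimum, and the joint covariance of
#' `(alpha, log theta)` is taken as the inverse observed information
#' (numerical Hessian) of the full likelihood at the optimum.
#'
#' @inheritParams profile_negloglik
#' @param family Variogram family: `"exponential"` (default), `"spherical"`,
#'   or `"cubic"`.
#' @param n_starts Number of grid starts from which full optimizations run.
#' @param control Passed to [stats::optim()] (Nelder-Mead); the default uses
#'   `reltol = 1e-10`.
#' @param hessian Compute the joint parameter covariance (needed for the
#'   parameter bootstrap). Set `FALSE` to skip, e.g. inside cross-validation.
#' @return An object of class `kriging_fit`: family, `theta` (nugget tau2,
#'   partial sill sigma2, range phi), `alpha`, `param_cov` on the
#'   `(alpha, log theta)` scale, `loglik`, plus the training data needed for
#'   prediction.
#' @export
fit_universal_kriging <- function(scores, conc_sqrt, coords, family = "exponential",
                                  n_starts = 3, control = list(), hessian = TRUE) {
  coords <- as_coord_matrix(coords)
  if (any(duplicated(coords))) {
    abort("Duplicate monitor coordinates are not allowed (singular covariance).")
  }
  X <- design_matrix(scores)
  y <- as.numeric(conc_sqrt)
  if (nrow(X) != length(y) || nrow(coords) != length(y)) {
    abort("scores, conc_sqrt and coords must have matching lengths.")
  }
  if (length(y) < ncol(X) + 3) abort("Too few monitors to fit the kriging model.")
  D <- dist_matrix(coords)

  # start grid from empirical variogram of OLS residuals
  ols <- lm.fit(X, y)
  v <- mean(ols$residuals^2)
  ev <- empirical_variogram(coords, ols$residuals)
  near <- ev$gamma[which.min(ev$dist)]
  tau0 <- min(max(near, 0.05 * v), 0.95 * v)
  pos <- D[upper.tri(D)]
  starts <- expand.grid(
    tau2 = pmax(tau0 * c(0.3, 1, 2.5), 1e-6 * v),
    sigma2 = pmax(v * c(0.2, 0.6, 1.2), 1e-6 * v),
    phi = quantile(pos, c(0.05, 0.25, 0.6), names = FALSE)
  )
  obj <- function(lt) {
    th <- exp(lt)
    if (!all(is.finite(th)) || th[3] <= 0) return(1e10)
    tryCatch(
      profile_negloglik_D(pmax(th, c(0, 0, 1e-8)), X, y, D, family),
      error = function(e) 1e10
    )
  }
  grid_lt <- log(as.matrix(starts))
  grid_val <- apply(grid_lt, 1, obj)
  ord <- order(grid_val)
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 1000), control)
  fits <- lapply(ord[seq_len(min(n_starts, length(ord)))], function(i) {
    tryCatch(optim(grid_lt[i, ], obj, method = "Nelder-Mead", control = ctrl),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("Universal kriging optimization failed from all starts.")
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  # polish
  pol <- optim(best$par, obj, method = "Nelder-Mead", control = ctrl)
  if (pol$value < best$value) best <- pol
  # floor the log-parameters: variance components at the boundary are kept
  # at a negligible but finite value so the log scale stays usable
  lt_floor <- c(log(1e-10 * v), log(1e-10 * v), log(1e-4 * max(D)))
  lt_hat <- pmax(best$par, lt_floor)
  theta_hat <- check_theta(exp(lt_hat))
  # parsimony guard: the partial sill and range add two parameters that
  # improve the maximized likelihood by ~1 nat on pure noise (and are
  # unidentified on the short-range ridge where a sill mimics the nugget).
  # Keep the spatial component only if it beats the pure-nugget (iid) model
  # by more than the AIC penalty for two parameters.
  iid_tol <- 2
  tau2_iid <- mean(lm.fit(X, y)$residuals^2)
  nll_iid <- profile_negloglik_D(c(tau2_iid, 0, 1), X, y, D, family)
  if (nll_iid <= best$value + iid_tol) {
    theta_hat <- check_theta(c(tau2_iid, 1e-10 * v, exp(lt_floor[3])))
    lt_hat <- log(theta_hat)
    best$value <- min(best$value, nll_iid)
  }
  prof <- profile_negloglik_D(theta_hat, X, y, D, family, return_alpha = TRUE)
  alpha <- setNames(prof$alpha, colnames(X))

  param_cov <- NULL
  if (isTRUE(hessian)) {
    p <- ncol(X)
    joint <- function(par) {
      a <- par[seq_len(p)]
      th <- exp(par[p + 1:3])
      tryCatch({
        S <- cov_matrix(pmax(th, c(0, 0, 1e-8)), D, family)
        U <- chol(S)
        r <- backsolve(U, y - X %*% a, transpose = TRUE)
        0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(r^2))
      }, error = function(e) 1e10)
    }
    H <- tryCatch(optimHess(c(alpha, lt_hat), joint), error = function(e) NULL)
    param_cov <- if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) MASS_ginv(H))
      nearest_psd(V)
    } else {
      matrix(NA_real_, p + 3, p + 3)
    }
    nm <- c(colnames(X), "log_tau2", "log_sigma2", "log_phi")
    dimnames(param_cov) <- list(nm, nm)
  }

  structure(list(
    family = family,
    theta = theta_hat,
    log_theta = setNames(lt_hat, c("log_tau2", "log_sigma2", "log_phi")),
    alpha = alpha,
    param_cov = param_cov,
    loglik = -best$value,
    convergence = best$convergence,
    scores_obs = X[, -1, drop = FALSE],
    conc_sqrt_obs = y,
    coords_obs = coords
  ), class = "kriging_fit")
}

# Moore-Penrose inverse without adding a MASS dependency for one call.
MASS_ginv <- function(H, tol = 1e-10) {
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  if (!any(pos)) return(matrix(0, nrow(H), ncol(H)))
  e$vectors[, pos, drop = FALSE] %*%
    ((1 / e$values[pos]) * t(e$vectors[, pos, drop = FALSE]))
}

#' @export
print.kriging_fit <- function(x, ...) {
  cat("Universal kriging fit (", x$family, " variogram)\n", sep = "")
  cat(sprintf("  nugget tau2   = %.5g\n", x$theta[["tau2"]]))
  cat(sprintf("  partial sill  = %.5g\n", x$theta[["sigma2"]]))
  cat(sprintf("  range phi     = %.5g km\n", x$theta[["phi"]]))
  cat(sprintf("  tau2/sigma2   = %.3g\n", x$theta[["tau2"]] / x$theta[["sigma2"]]))
  cat(sprintf("  log-likelihood = %.4f  (n = %d monitors)\n",
    x$loglik, length(x$conc_sqrt_obs)))
  invisible(x)
}

#' @export
tidy.kriging_fit <- function(x, ...) {
  est <- c(x$alpha, x$theta)
  tibble(
    term = names(est),
    estimate = as.numeric(est),
    type = c(rep("mean", length(x$alpha)), rep("variogram", 3))
  )
}

#' @export
glance.kriging_fit <- function(x, ...) {
  tibble(
    family = x$family,
    logLik = x$loglik,
    nugget = x$theta[["tau2"]],
    partial_sill = x$theta[["sigma2"]],
    range_km = x$theta[["phi"]],
    nugget_sill_ratio = x$theta[["tau2"]] / x$theta[["sigma2"]],
    n_monitors = length(x$conc_sqrt_obs),
    convergence = x$convergence
  )
}

#' Predict exposure at new locations by universal kriging
#'
#' Conditional-mean prediction
#' `T alpha + C(theta) Sigma(theta)^-1 (X* - T* alpha)` where `C` is the
#' cross-covariance between new and observed sites (partial sill only, no
#' nugget). Untransformed-scale predictions are the squared sqrt-scale
#' predictions, with negative sqrt-scale values floored at zero first (a
#' message reports how many were floored).
#'
#' @param kf A [fit_universal_kriging()] fit.
#' @param scores_new PLS scores at prediction locations.
#' @param coords_new Prediction coordinates (n x 2, km).
#' @param se Also return the conditional (kriging) variance given the fitted
#'   parameters, as column `pred_var` (sqrt scale).
#' @param ids Optional location ids for the output.
#' @return A tibble of class `exposure_predictions` with columns `id`,
#'   `pred_sqrt`, `pred_raw`, `method` (and `pred_var` if `se = TRUE`).
#' @export
predict_uk <- function(kf, scores_new, coords_new, se = FALSE, ids = NULL) {
  stopifnot(inherits(kf, "kriging_fit"))
  Xn <- design_matrix(scores_new)
  coords_new <- as_coord_matrix(coords_new)
  if (ncol(Xn) != length(kf$alpha)) {
    abort("scores_new has a different number of columns than the fitted scores.")
  }
  if (nrow(Xn) != nrow(coords_new)) abort("scores_new and coords_new disagree in length.")
  Xo <- design_matrix(kf$scores_obs)
  D <- dist_matrix(kf$coords_obs)
  S <- cov_matrix(kf$theta, D, kf$family)
  U <- chol_jitter(S)
  resid <- kf$conc_sqrt_obs - as.numeric(Xo %*% kf$alpha)
  Cno <- cross_cov(kf$theta, dist_matrix(coords_new, kf$coords_obs), kf$family)
  w <- backsolve(U, backsolve(U, resid, transpose = TRUE))
  pred <- as.numeric(Xn %*% kf$alpha) + as.numeric(Cno %*% w)
  out <- exposure_predictions(pred, "pls_uk", ids)
  if (se) {
    # conditional variance given the fitted parameters (simple-kriging form)
    V <- backsolve(U, t(Cno), transpose = TRUE)
    out$pred_var <- pmax(kf$theta[["tau2"]] + kf$theta[["sigma2"]] - colSums(V^2), 0)
  }
  out
}

exposure_predictions <- function(pred_sqrt, method, ids = NULL) {
  n_neg <- sum(pred_sqrt < 0)
  if (n_neg > 0) {
    inform(paste0(n_neg, " negative sqrt-scale prediction(s) floored at 0 before squaring."))
  }
  ps <- pmax(pred_sqrt, 0)
  tibble(
    id = if (is.null(ids)) seq_along(pred_sqrt) else ids,
    pred_sqrt = pred_sqrt,
    pred_raw = ps^2,
    method = method
  ) %>% structure(class = c("exposure_predictions", class(tibble())))
}

#' Nearest-monitor exposure estimates
#'
#' Baseline predictor: each new site takes the observed value of its
#' Euclidean-nearest monitor; distance ties are broken by the lowest
#' monitor id.
#'
#' @param coords_obs Monitor coordinates (n x 2, km).
#' @param conc_obs Observed sqrt-scale concentrations at monitors.
#' @param coords_new Prediction coordinates.
#' @param ids_obs Monitor ids used for tie-breaking (default `1:n`).
#' @param ids Optional output ids.
#' @return An `exposure_predictions` tibble, `method = "nearest_monitor"`.
#' @export
nearest_monitor <- function(coords_obs, conc_obs, coords_new,
                            ids_obs = NULL, ids = NULL) {
  coords_obs <- as_coord_matrix(coords_obs)
  coords_new <- as_coord_matrix(coords_new)
  if (nrow(coords_obs) < 1) abort("Need at least one monitor.")
  if (is.null(ids_obs)) ids_obs <- seq_len(nrow(coords_obs))
  Dno <- dist_matrix(coords_new, coords_obs)
  pick <- apply(Dno, 1, function(d) {
    cand <- which(d <= min(d) + 1e-12)
    cand[which.min(ids_obs[cand])]
  })
  exposure_predictions(as.numeric(conc_obs)[pick], "nearest_monitor", ids)
}
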