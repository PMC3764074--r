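#' Scenario configuration for synthetic two-stage studies
#'
#' Bundles the ground-truth parameters of a synthetic study: the exposure
#' surface is a Gaussian random field on a square region with mean linear in
#' a small number of smooth latent factors (the structure PLS assumes) and a
#' residual with nugget/partial-sill/range variogram; health outcomes are
#' linear in the untransformed true exposure plus adjustment covariates.
#'
#' @param n_monitors Number of monitors (quasi-uniform over the region).
#' @param n_subjects Number of study subjects.
#' @param region_size Side of the square study region, km. The default
#'   (3000 km) is continental scale, comparable to a national monitoring
#'   network.
#' @param cluster_fraction Proportion of subjects placed in tight urban
#'   clusters (the rest are uniform over the region).
#' @param n_clusters Number of urban clusters.
#' @param cluster_sd SD of subject scatter around a cluster center, km.
#' @param p_covariates Number of geographic covariates.
#' @param n_latent Number of true low-rank covariate factors carrying the
#'   exposure signal (`<= p_covariates`).
#' @param n_distance Number of distance-type (positive, heavy-tailed)
#'   covariates appended for pre-processing tests.
#' @param cov_noise_sd SD of independent noise added to the factor-driven
#'   covariates.
#' @param alpha_true Mean coefficients, length `n_latent + 1` (intercept
#'   first), sqrt-concentration units per latent-factor unit.
#' @param theta_true `(tau2, sigma2, phi)`: nugget, partial sill (sqrt-scale
#'   concentration variance) and range (km) of the residual field.
#' @param variogram_family `"exponential"`, `"spherical"` or `"cubic"`.
#' @param beta_true Health coefficients `(beta0, beta_x, beta_z...)`; the
#'   number of adjustment covariates `Z` is `length(beta_true) - 2`.
#' @param sigma_y Health-outcome noise SD (outcome units).
#' @param misspecified Add nonlinear terms to the covariate table so the
#'   linear-in-factors PLS assumption is (mildly) violated.
#' @param seed Integer root seed; every generator below is a pure function of
#'   the configuration including this seed.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_monitors = 150,
                            n_subjects = 500,
                            region_size = 3000,
                            cluster_fraction = 0.9,
                            n_clusters = 6,
                            cluster_sd = 30,
                            p_covariates = 50,
                            n_latent = 2,
                            n_distance = 5,
                            cov_noise_sd = 0.5,
                            alpha_true = c(0.88, 0.07, 0.05),
                            theta_true = c(0.0007, 0.0251, 2145),
                            variogram_family = "exponential",
                            beta_true = c(0.68, 0.055, 0.02, -0.01),
                            sigma_y = 0.19,
                            misspecified = FALSE,
                            seed = 1L) {
  cfg <- list(
    n_monitors = as.integer(n_monitors), n_subjects = as.integer(n_subjects),
    region_size = region_size, cluster_fraction = cluster_fraction,
    n_clusters = as.integer(n_clusters), cluster_sd = cluster_sd,
    p_covariates = as.integer(p_covariates), n_latent = as.integer(n_latent),
    n_distance = as.integer(n_distance), cov_noise_sd = cov_noise_sd,
    alpha_true = alpha_true, theta_true = check_theta(theta_true),
    variogram_family = variogram_family, beta_true = beta_true,
    sigma_y = sigma_y, misspecified = isTRUE(misspecified),
    seed = as.integer(seed)
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  if (cfg$region_size <= 0) abort("region_size must be > 0.")
  if (cfg$n_monitors < 1 || cfg$n_subjects < 1 || cfg$p_covariates < 1 ||
    cfg$n_latent < 1 || cfg$n_clusters < 1) {
    abort("All counts must be >= 1.")
  }
  if (cfg$n_latent > cfg$p_covariates) abort("n_latent must be <= p_covariates.")
  if (cfg$cluster_fraction < 0 || cfg$cluster_fraction > 1) {
    abort("cluster_fraction must be in [0, 1].")
  }
  if (length(cfg$alpha_true) != cfg$n_latent + 1) {
    abort("alpha_true must have length n_latent + 1 (intercept first).")
  }
  if (length(cfg$beta_true) < 2) abort("beta_true needs at least (beta0, beta_x).")
  if (cfg$sigma_y < 0) abort("sigma_y must be >= 0.")
  if (!cfg$variogram_family %in% c("exponential", "spherical", "cubic")) {
    abort("Unknown variogram family.")
  }
  invisible(cfg)
}

#' Scenario presets
#'
#' `scenario_s_like()` uses the strong-spatial-structure variogram regime
#' (tau2 = 0.0007, sigma2 = 0.0251, phi = 2145 km) typical of a secondary,
#' regionally transported pollutant; `scenario_ec_like()` the weak-spatial
#' regime (tau2 = 0.0074, sigma2 = 0.0025, phi = 413 km) typical of a
#' locally generated primary pollutant; `scenario_no_spatial()` removes the
#' spatially structured residual entirely (sigma2 = 0), the regime in which
#' exposure prediction error is almost pure independent Berkson error.
#'
#' @param ... Overrides passed on to [scenario_config()].
#' @export
scenario_s_like <- function(...) {
  scenario_config(theta_true = c(0.0007, 0.0251, 2145), ...)
}

#' @rdname scenario_s_like
#' @export
scenario_ec_like <- function(...) {
  scenario_config(theta_true = c(0.0074, 0.0025, 413), ...)
}

#' @rdname scenario_s_like
#' @export
scenario_no_spatial <- function(...) {
  scenario_config(theta_true = c(0.0074, 0, 413), ...)
}

#' Generate monitor and subject locations
#'
#' Monitors are quasi-uniform (jittered grid) over the square region;
#' `cluster_fraction` of the subjects are scattered around a small number of
#' urban cluster centers, the remainder uniform.
#'
#' @param cfg A [scenario_config()].
#' @return List with `monitors` and `subjects` coordinate tibbles
#'   (`id`, `x`, `y`) and the `cluster_centers` matrix.
#' @export
generate_locations <- function(cfg) {
  validate_scenario_config(cfg)
  L <- cfg$region_size
  withr::with_seed(child_seed(cfg$seed, 11), {
    # jittered-grid monitors: quasi-uniform coverage
    g <- ceiling(sqrt(cfg$n_monitors))
    cell <- L / g
    grid <- expand.grid(ix = seq_len(g) - 1, iy = seq_len(g) - 1)
    grid <- grid[sample.int(nrow(grid), cfg$n_monitors), , drop = FALSE]
    mon <- tibble(
      id = seq_len(cfg$n_monitors),
      x = (grid$ix + runif(cfg$n_monitors)) * cell,
      y = (grid$iy + runif(cfg$n_monitors)) * cell
    )
    centers <- cbind(runif(cfg$n_clusters, 0.15 * L, 0.85 * L),
      runif(cfg$n_clusters, 0.15 * L, 0.85 * L))
    n_cl <- round(cfg$cluster_fraction * cfg$n_subjects)
    assign_cl <- sample.int(cfg$n_clusters, n_cl, replace = TRUE)
    sx <- c(pmin(pmax(centers[assign_cl, 1] + rnorm(n_cl, 0, cfg$cluster_sd), 0), L),
      runif(cfg$n_subjects - n_cl, 0, L))
    sy <- c(pmin(pmax(centers[assign_cl, 2] + rnorm(n_cl, 0, cfg$cluster_sd), 0), L),
      runif(cfg$n_subjects - n_cl, 0, L))
    sub <- tibble(id = seq_len(cfg$n_subjects), x = sx, y = sy)
  })
  list(monitors = mon, subjects = sub, cluster_centers = centers)
}

#' Generate geographic covariates at a set of locations
#'
#' Covariates are latent-factor loadings times smooth spatial factors plus
#' independent noise, so a low-dimensional linear combination of the table
#' carries the exposure signal (the structure PLS assumes). A configurable
#' number of distance-type columns (`dist_*`: positive, heavy-tailed
#' distances in km to random landmarks) is appended for pre-processing.
#'
#' @param coords Coordinate tibble or matrix for all locations (row-aligned
#'   with the output).
#' @param cfg A [scenario_config()].
#' @return List with `covariates` (tibble `cov_1..cov_p`, `dist_1..`),
#'   `factors` (the n x n_latent latent factor matrix, the generator's true
#'   scores) and `loadings`.
#' @export
generate_covariates <- function(coords, cfg) {
  validate_scenario_config(cfg)
  xy <- as_coord_matrix(coords)
  if (nrow(xy) == 0) abort("Empty coordinate set.")
  L <- cfg$region_size
  withr::with_seed(child_seed(cfg$seed, 23), {
    # smooth spatial factors: random low-frequency cosine features
    n_feat <- 8L
    Fm <- matrix(0, nrow(xy), cfg$n_latent)
    for (l in seq_len(cfg$n_latent)) {
      freq <- matrix(rnorm(2 * n_feat, 0, 2 * pi / L), n_feat, 2)
      phase <- runif(n_feat, 0, 2 * pi)
      amp <- rnorm(n_feat)
      f <- sqrt(2 / n_feat) * (cos(xy %*% t(freq) + matrix(phase, nrow(xy), n_feat,
        byrow = TRUE)) %*% amp)
      Fm[, l] <- as.numeric(scale(f))
    }
    loadings <- matrix(rnorm(cfg$p_covariates * cfg$n_latent), cfg$p_covariates)
    covs <- Fm %*% t(loadings) +
      cfg$cov_noise_sd * matrix(rnorm(nrow(xy) * cfg$p_covariates), nrow(xy))
    if (cfg$misspecified) {
      nl <- seq_len(min(5L, cfg$p_covariates))
      covs[, nl] <- covs[, nl] + 0.3 * Fm[, 1]^2
    }
    colnames(covs) <- paste0("cov_", seq_len(cfg$p_covariates))
    out <- as_tibble(covs)
    if (cfg$n_distance > 0) {
      # local-feature distances (km): lognormal, mostly < 10 km, heavy upper
      # tail, mildly tied to the first latent factor (urban features cluster)
      Dl <- matrix(
        exp(rnorm(nrow(xy) * cfg$n_distance, 0, 1.3)),
        nrow(xy), cfg$n_distance
      ) * exp(-0.3 * Fm[, 1])
      colnames(Dl) <- paste0("dist_", seq_len(cfg$n_distance))
      out <- bind_cols(out, as_tibble(Dl))
    }
  })
  list(covariates = out, factors = Fm, loadings = loadings)
}

#' Draw the true sqrt-scale exposure surface at all locations
#'
#' Single joint Gaussian draw over monitors and subjects together: mean
#' `cbind(1, scores) %*% alpha_true` plus a zero-mean field with covariance
#' `tau2 I + sigma2 rho(d/phi)`.
#'
#' @param coords_all Coordinates for all sites (monitors then subjects).
#' @param scores_all True score (latent factor) matrix, row-aligned.
#' @param cfg A [scenario_config()].
#' @param seed Optional seed override (defaults to a stream derived from
#'   `cfg$seed`).
#' @return Numeric vector of sqrt-scale exposures at all sites.
#' @export
generate_true_surface <- function(coords_all, scores_all, cfg, seed = NULL) {
  validate_scenario_config(cfg)
  xy <- as_coord_matrix(coords_all)
  S <- as.matrix(scores_all)
  if (nrow(S) != nrow(xy)) abort("scores_all must be row-aligned with coords_all.")
  mu <- as.numeric(cbind(1, S) %*% cfg$alpha_true)
  th <- cfg$theta_true
  if (is.null(seed)) seed <- child_seed(cfg$seed, 37)
  withr::with_seed(seed, z <- rnorm(nrow(xy)))
  if (th[["tau2"]] == 0 && th[["sigma2"]] == 0) return(mu)
  if (th[["sigma2"]] == 0) return(mu + sqrt(th[["tau2"]]) * z)
  Sg <- cov_matrix(th, dist_matrix(xy), cfg$variogram_family)
  U <- chol_jitter(Sg)
  mu + as.numeric(crossprod(U, z))
}

#' Generate health outcomes from true exposures
#'
#' `Y = beta0 + W beta_x + Z beta_z + eps`, `eps ~ N(0, sigma_y^2)` iid,
#' where `W` is the true exposure on the untransformed scale (the square of
#' the sqrt-scale value).
#'
#' @param true_exposure_sqrt True sqrt-scale exposures at subjects.
#' @param Z Adjustment-covariate matrix (may have zero columns).
#' @param cfg A [scenario_config()].
#' @param seed Optional seed override.
#' @return Numeric outcome vector.
#' @export
generate_health <- function(true_exposure_sqrt, Z, cfg, seed = NULL) {
  validate_scenario_config(cfg)
  W <- as.numeric(true_exposure_sqrt)^2
  Z <- as.matrix(Z)
  if (nrow(Z) > 0 && nrow(Z) != length(W)) abort("Z and exposures are not row-aligned.")
  bz <- cfg$beta_true[-(1:2)]
  if (ncol(Z) != length(bz)) abort("Z has a different number of columns than beta_z.")
  if (is.null(seed)) seed <- child_seed(cfg$seed, 53)
  withr::with_seed(seed, eps <- rnorm(length(W), 0, cfg$sigma_y))
  mu <- cfg$beta_true[1] + W * cfg$beta_true[2]
  if (ncol(Z) > 0) mu <- mu + as.numeric(Z %*% bz)
  mu + eps
}

#' Simulate a complete synthetic two-stage study
#'
#' Runs the full generative chain: locations, covariates, one joint draw of
#' the true exposure surface at monitors and subjects, and health outcomes.
#' Monitors observe their own realization of the field (their draw *is* the
#' observation); subjects keep their true exposures for validation.
#'
#' @param cfg A [scenario_config()].
#' @return Object of class `synthetic_study`: `monitors` (id, x, y,
#'   conc_sqrt, conc_raw), `covariates_monitors`, `subjects` (id, x, y,
#'   true_sqrt, true_raw, y_outcome, z_*), `covariates_subjects`,
#'   `factors_*` (true latent scores) and the `config`.
#' @export
simulate_study <- function(cfg) {
  validate_scenario_config(cfg)
  loc <- generate_locations(cfg)
  nm <- cfg$n_monitors
  coords_all <- bind_rows(loc$monitors[c("x", "y")], loc$subjects[c("x", "y")])
  gc <- generate_covariates(coords_all, cfg)
  x_all <- generate_true_surface(coords_all, gc$factors, cfg)
  x_mon <- x_all[seq_len(nm)]
  x_sub <- x_all[-seq_len(nm)]
  n_neg <- sum(x_mon < 0)
  if (n_neg > 0) {
    warn(paste0(n_neg, " negative sqrt-scale monitor draws clamped at 0; ",
      "consider a larger mean (alpha_true[1])."))
    x_mon <- pmax(x_mon, 0)
  }
  q <- length(cfg$beta_true) - 2L
  Z <- if (q > 0) {
    withr::with_seed(child_seed(cfg$seed, 71),
      matrix(rnorm(cfg$n_subjects * q), cfg$n_subjects, q,
        dimnames = list(NULL, paste0("z_", seq_len(q)))))
  } else {
    matrix(0, cfg$n_subjects, 0)
  }
  outcome <- generate_health(x_sub, Z, cfg)
  monitors <- loc$monitors %>% mutate(conc_sqrt = x_mon, conc_raw = x_mon^2)
  subjects <- loc$subjects %>%
    mutate(true_sqrt = x_sub, true_raw = x_sub^2,
      y_outcome = .env$outcome) %>%
    bind_cols(as_tibble(Z))
  structure(list(
    monitors = monitors,
    covariates_monitors = bind_cols(tibble(id = monitors$id),
      gc$covariates[seq_len(nm), ]),
    subjects = subjects,
    covariates_subjects = bind_cols(tibble(id = subjects$id),
      gc$covariates[-seq_len(nm), ]),
    factors_monitors = gc$factors[seq_len(nm), , drop = FALSE],
    factors_subjects = gc$factors[-seq_len(nm), , drop = FALSE],
    config = cfg
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic two-stage study\n")
  cat(sprintf("  %d monitors, %d subjects on a %.0f km square\n",
    cfg$n_monitors, cfg$n_subjects, cfg$region_size))
  cat(sprintf("  %d covariates (%d latent factors), theta = (%.4g, %.4g, %.4g), %s\n",
    cfg$p_covariates + cfg$n_distance, cfg$n_latent, cfg$theta_true[1],
    cfg$theta_true[2], cfg$theta_true[3], cfg$variogram_family))
  invisible(x)
}
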