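# Shared small fixtures built in code.

# Tiny study for fast end-to-end tests.
small_study <- function(seed = 1, ...) {
  simulate_study(scenario_config(
    n_monitors = 60, n_subjects = 80, p_covariates = 15, n_distance = 3,
    seed = seed, ...))
}

# Random monitor layout + iid-score field for direct kriging tests.
sim_field <- function(n, theta, family = "exponential", seed = 1,
                      L = 2000, k = 2) {
  withr::with_seed(seed, {
    coords <- cbind(runif(n, 0, L), runif(n, 0, L))
    scores <- matrix(rnorm(n * k), n, k)
  })
  mu <- 0.9 + scores %*% rep(0.1, k)
  S <- theta[1] * diag(n) +
    theta[2] * plskrige::corr_function(family, as.matrix(dist(coords)), theta[3])
  withr::with_seed(seed + 1, z <- rnorm(n))
  x <- as.numeric(mu + t(chol(S)) %*% z)
  list(coords = coords, scores = scores, x = x)
}

# Raw covariate table with known screening targets.
prep_fixture <- function() {
  withr::with_seed(42, tibble::tibble(
    id = 1:100,
    keep_normal = rnorm(100),
    mostly_same = c(rep(1, 86), rnorm(14)),          # > 85% identical
    boundary_85 = c(rep(1, 85), rnorm(15)),          # exactly 85%: retained
    constant = rep(3.3, 100),
    outlier = c(rnorm(99), 50),                      # z > 7
    dist_a = exp(rnorm(100, 0, 1)),
    dist_b = exp(rnorm(100, 0.5, 1))
  ))
}
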