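#' Fit the linear health model by OLS
#'
#' Fits `E(Y) = beta0 + W beta_x + Z beta_z` by ordinary least squares, where
#' `W` is the exposure of interest on the untransformed scale and `Z` a
#' matrix of adjustment covariates. Rows with any missing value are dropped
#' (complete-case analysis) and counted. Standard errors are the classical
#' homoskedastic OLS ones; confidence intervals use the normal approximation
#' of [normal_ci()].
#'
#' @param y Outcome vector.
#' @param w Exposure vector (untransformed scale).
#' @param z Optional adjustment-covariate matrix/data frame (or `NULL`).
#' @param level Confidence level (default 0.95).
#' @return Object of class `health_fit` with a `coefficients` tibble (term,
#'   estimate, se, ci_lo, ci_hi), `beta_x`, `sigma_resid`, `n_used`,
#'   `n_dropped`, and the model pieces needed downstream.
#' @export
fit_health_ols <- function(y, w, z = NULL, level = 0.95) {
  y <- as.numeric(y)
  w <- as.numeric(w)
  if (length(w) != length(y)) abort("y and w disagree in length.")
  Z <- if (is.null(z)) matrix(0, length(y), 0) else as.matrix(z)
  if (ncol(Z) > 0 && nrow(Z) != length(y)) abort("z is not row-aligned with y.")
  if (ncol(Z) > 0 && is.null(colnames(Z))) colnames(Z) <- paste0("z_", seq_len(ncol(Z)))
  X <- cbind(`(Intercept)` = 1, w = w, Z)
  cc <- complete.cases(cbind(y, X))
  n_dropped <- sum(!cc)
  if (n_dropped > 0) inform(paste0(n_dropped, " incomplete row(s) dropped."))
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p) abort("Too few complete cases for the health model.")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("Rank-deficient health-model design; collinear column(s): ",
      paste(bad, collapse = ", ")))
  }
  est <- qr.coef(qrX, y)
  res <- y - X %*% est
  sigma2 <- sum(res^2) / (n - p)
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  ci <- normal_ci(est, se, level)
  coefs <- tibble(term = colnames(X), estimate = as.numeric(est),
    se = as.numeric(se), ci_lo = ci[, 1], ci_hi = ci[, 2])
  structure(list(
    coefficients = coefs,
    beta0 = unname(est[1]), beta_x = unname(est[2]),
    beta_z = if (p > 2) est[-(1:2)] else numeric(0),
    se_naive = setNames(as.numeric(se), colnames(X)),
    sigma_resid = sqrt(sigma2),
    n_used = n, n_dropped = n_dropped, level = level,
    z_names = colnames(Z)
  ), class = "health_fit")
}

#' Normal-approximation confidence interval
#'
#' `estimate +/- z * se`. For the conventional 95% level the multiplier is
#' the rounded z = 1.96 (the convention used when reporting intervals to two
#' or three decimals); other levels use the exact normal quantile.
#'
#' @param estimate,se Numeric vectors (recycled).
#' @param level Confidence level in (0, 1).
#' @return Two-column matrix `(lower, upper)`.
#' @export
normal_ci <- function(estimate, se, level = 0.95) {
  if (length(level) != 1 || is.na(level) || level <= 0 || level >= 1) {
    abort("level must be in (0, 1).")
  }
  if (any(se < 0)) abort("se must be >= 0.")
  z <- if (isTRUE(all.equal(level, 0.95))) 1.96 else qnorm((1 + level) / 2)
  cbind(lower = estimate - z * se, upper = estimate + z * se)
}

#' @export
print.health_fit <- function(x, ...) {
  cat(sprintf("Health model (OLS), n = %d used, %d dropped\n", x$n_used, x$n_dropped))
  print(x$coefficients)
  cat(sprintf("Residual SD: %.4g\n", x$sigma_resid))
  invisible(x)
}

#' @export
tidy.health_fit <- function(x, ...) {
  dplyr::rename(x$coefficients, std.error = "se", conf.low = "ci_lo",
    conf.high = "ci_hi")
}

#' @export
glance.health_fit <- function(x, ...) {
  tibble(n_used = x$n_used, n_dropped = x$n_dropped,
    sigma_resid = x$sigma_resid, level = x$level)
}
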