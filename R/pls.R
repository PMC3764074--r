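#' Fit partial least squares scores for sqrt-scale concentrations
#'
#' Univariate-response PLS (NIPALS with deflation) of the standardized
#' geographic covariates `R*` on the sqrt-scale concentrations: finds a
#' `p x k` weight matrix `H` such that the scores `T* = R* H` are linear
#' combinations of the covariates maximizing covariance with the response,
#' then regresses the response on the scores by OLS.
#'
#' The covariates are expected to be already standardized (see
#' [prep_covariates()]); no further centering of `R*` is applied, so scores at
#' new locations are exactly `T = R H` once the new covariates are
#' standardized with the *monitor* centers and scales.
#'
#' @param covariates Standardized covariate table (tibble or matrix; an `id`
#'   column is ignored) at monitor locations.
#' @param conc_sqrt Numeric response vector (sqrt-scale concentrations).
#' @param k Number of PLS components, `1 <= k <= min(p, n - 1)`.
#' @return An object of class `pls_fit` with the weight matrix `H`, training
#'   scores, score-regression coefficients and the derived single weight
#'   vector `m` (see [pls_weight_vector()]).
#' @export
fit_pls <- function(covariates, conc_sqrt, k) {
  X <- as_cov_matrix(covariates)
  y <- as.numeric(conc_sqrt)
  if (nrow(X) != length(y)) abort("covariates and conc_sqrt disagree in length.")
  p <- ncol(X)
  if (k < 1 || k > min(p, nrow(X) - 1)) {
    abort(sprintf("k must be between 1 and min(p, n - 1) = %d.", min(p, nrow(X) - 1)))
  }
  y_mean <- mean(y)
  Xd <- X
  yd <- y - y_mean
  W <- matrix(0, p, k)
  P <- matrix(0, p, k)
  Tm <- matrix(0, nrow(X), k)
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {
      # response fully deflated; pad with an arbitrary orthogonal direction
      w <- rep(0, p); w[a] <- 1
    } else {
      w <- w / nw
    }
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-14) abort("Degenerate PLS component; reduce k.")
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
  }
  # weights applying directly to the (un-deflated) covariates: T* = X H
  H <- W %*% solve(crossprod(P, W))
  colnames(H) <- paste0("score_", seq_len(k))
  rownames(H) <- colnames(X)
  scores <- X %*% H
  fit_ols <- lm.fit(cbind(1, scores), y)
  coefs <- setNames(fit_ols$coefficients, c("(Intercept)", colnames(H)))
  structure(list(
    k = k,
    H = H,
    scores = scores,
    coef = coefs,
    y_mean = y_mean,
    fitted = as.numeric(cbind(1, scores) %*% coefs),
    y = y,
    covariate_names = colnames(X)
  ), class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("PLS fit:", x$k, "component(s),", length(x$covariate_names), "covariates\n")
  invisible(x)
}

#' Project PLS scores at new locations
#'
#' Computes `T = R H` for new covariates standardized with the monitor-fit
#' centers and scales. Projecting the training covariates reproduces the
#' training scores exactly.
#'
#' @param fit A [fit_pls()] object.
#' @param covariates_new Standardized covariates at new locations (columns
#'   must match the training covariates).
#' @return Matrix of scores (`n x k`).
#' @export
project_scores <- function(fit, covariates_new) {
  stopifnot(inherits(fit, "pls_fit"))
  X <- as_cov_matrix(covariates_new)
  if (ncol(X) != nrow(fit$H)) {
    abort("covariates_new has a different number of columns than the training covariates.")
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), fit$covariate_names)) {
    abort("covariates_new columns do not match the training covariates.")
  }
  X %*% fit$H
}

#' PLS-only exposure predictions
#'
#' Pure land-use-regression comparator: fitted values from the OLS regression
#' of sqrt-scale concentration on the PLS scores, evaluated at the projected
#' scores of the new locations (no kriging of the residuals).
#'
#' @inheritParams project_scores
#' @param ids Optional output ids.
#' @return An `exposure_predictions` tibble, `method = "pls_only"`.
#' @export
predict_pls_only <- function(fit, covariates_new, ids = NULL) {
  scores <- project_scores(fit, covariates_new)
  pred <- as.numeric(cbind(1, scores) %*% fit$coef)
  exposure_predictions(pred, "pls_only", ids)
}

#' Collapse a PLS fit into a single covariate weight vector
#'
#' Returns the `p x 1` vector `m` such that `R m + intercept` equals the
#' PLS-only predictions for standardized covariates `R`. Each element is the
#' total weight of one geographic covariate in the prediction; its sign says
#' whether higher covariate values push predicted exposure up or down.
#'
#' @param fit A [fit_pls()] object.
#' @return Named numeric vector `m` with attribute `"intercept"`.
#' @export
pls_weight_vector <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  m <- drop(fit$H %*% fit$coef[-1])
  names(m) <- fit$covariate_names
  attr(m, "intercept") <- unname(fit$coef[1])
  m
}

#' @export
tidy.pls_fit <- function(x, ...) {
  m <- pls_weight_vector(x)
  tibble(covariate = names(m), weight = as.numeric(m))
}

#' @export
glance.pls_fit <- function(x, ...) {
  tibble(
    k = x$k,
    p = length(x$covariate_names),
    n = nrow(x$scores),
    r_squared = 1 - sum((x$y - x$fitted)^2) / sum((x$y - x$y_mean)^2)
  )
}
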