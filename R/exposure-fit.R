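#' Fit the full first-stage exposure model
#'
#' Convenience wrapper running covariate pre-processing, PLS with `k`
#' components, and profile-ML universal kriging on the monitors of a study,
#' then projecting PLS scores to the subject locations. This is the bundle
#' the health stage and the measurement-error correction consume.
#'
#' @param study A [simulate_study()] object or a list with `monitors`,
#'   `covariates_monitors`, `subjects`, `covariates_subjects`.
#' @param k Number of PLS components.
#' @param family Variogram family.
#' @param prep_args Extra arguments to [prep_covariates()].
#' @param hessian Compute the joint parameter covariance (needed for the
#'   parameter bootstrap).
#' @return Object of class `exposure_fit`: `prep`, `pls`, `kriging`,
#'   `scores_subjects`, `coords_subjects`.
#' @export
fit_exposure <- function(study, k = 2, family = "exponential",
                         prep_args = list(), hessian = TRUE) {
  mon <- study$monitors
  prep <- do.call(prep_covariates, c(list(study$covariates_monitors), prep_args))
  pls <- fit_pls(prep$table, mon$conc_sqrt, k)
  kf <- fit_universal_kriging(pls$scores, mon$conc_sqrt, mon[c("x", "y")],
    family = family, hessian = hessian)
  cov_sub <- apply_prep(prep, study$covariates_subjects)
  structure(list(
    prep = prep, pls = pls, kriging = kf,
    scores_subjects = project_scores(pls, cov_sub),
    coords_subjects = as_coord_matrix(study$subjects)
  ), class = "exposure_fit")
}

#' Predict exposure at the subject locations of a study
#'
#' @param efit An [fit_exposure()] object.
#' @param method `"pls_uk"` (default), `"pls_only"` or `"nearest_monitor"`.
#' @param ids Optional output ids.
#' @return An `exposure_predictions` tibble.
#' @export
predict_subjects <- function(efit, method = c("pls_uk", "pls_only", "nearest_monitor"),
                             ids = NULL) {
  method <- match.arg(method)
  kf <- efit$kriging
  switch(method,
    pls_uk = predict_uk(kf, efit$scores_subjects, efit$coords_subjects, ids = ids),
    pls_only = {
      pred <- as.numeric(cbind(1, efit$scores_subjects) %*% efit$pls$coef)
      exposure_predictions(pred, "pls_only", ids)
    },
    nearest_monitor = nearest_monitor(kf$coords_obs, kf$conc_sqrt_obs,
      efit$coords_subjects, ids = ids)
  )
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("Two-stage exposure fit\n")
  print(x$pls)
  print(x$kriging)
  invisible(x)
}
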