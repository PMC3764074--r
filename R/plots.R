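# ggplot2 visualisations of the main result types.

#' @export
autoplot.cv_results <- function(object, ...) {
  tab <- tidy(object) %>% filter(!is.na(.data$k))
  nm <- tidy(object) %>% filter(is.na(.data$k))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$k, y = .data$rmsep,
    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PLS components (k)", y = "Cross-validated RMSEP (sqrt scale)",
      colour = NULL, title = "Model selection by 10-fold CV")
  if (nrow(nm) > 0) {
    p <- p + ggplot2::geom_hline(data = nm,
      ggplot2::aes(yintercept = .data$rmsep, colour = .data$method),
      linetype = "dashed")
  }
  p
}

#' @export
autoplot.kriging_fit <- function(object, n_bins = 12, ...) {
  Xo <- design_matrix(object$scores_obs)
  resid <- object$conc_sqrt_obs - as.numeric(Xo %*% object$alpha)
  ev <- empirical_variogram(object$coords_obs, resid, n_bins = n_bins)
  dd <- seq(1e-6, max(ev$dist), length.out = 200)
  fitted <- tibble(dist = dd,
    gamma = semivariogram(object$family, object$theta, dd))
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$dist, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::geom_line(data = fitted, linewidth = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "Distance (km)", y = "Semivariance",
      size = "Pairs", title = paste0("Fitted ", object$family, " variogram"))
}

#' @export
autoplot.bootstrap_result <- function(object, ...) {
  tab <- tibble(beta = object$beta_draws)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$beta_naive, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$beta_corrected,
      colour = "steelblue", linetype = "dashed") +
    ggplot2::labs(x = expression(hat(beta)[x]), y = "Replicates",
      title = sprintf("Parameter bootstrap draws (lambda = %g)", object$lambda))
}

#' @export
autoplot.simex_result <- function(object, ...) {
  grid <- seq(0, max(object$table$lambda, object$at), length.out = 100)
  curve <- tibble(lambda = grid,
    bias = as.numeric(outer(grid, seq_along(object$coef) - 1, "^") %*% object$coef))
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$lambda, y = .data$bias)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(data = tibble(lambda = object$at, bias = object$bias_at),
      colour = "firebrick", shape = 4, size = 3) +
    ggplot2::labs(x = expression(lambda), y = "Estimated bias",
      title = "SIMEX bias extrapolation")
}

#' Scatter plot of predicted versus observed concentrations
#'
#' @param cv_results A [cross_validate()] result.
#' @param method,k Which candidate's held-out predictions to show (defaults
#'   to the [select_model()] choice).
#' @return A ggplot object.
#' @export
plot_cv_predictions <- function(cv_results, method = NULL, k = NULL) {
  if (is.null(method)) {
    sel <- select_model(cv_results)
    method <- sel$method; k <- sel$k
  }
  row <- filter(as_tibble(cv_results), .data$method == !!method,
    (is.na(.data$k) & is.na(!!k)) | .data$k %in% !!k)
  if (nrow(row) == 0) abort("No matching CV candidate.")
  tab <- row$predictions[[1]]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Observed (sqrt scale)", y = "Held-out prediction",
      title = sprintf("%s, k = %s: RMSEP %.3g, R2 %.2f", method,
        ifelse(is.na(row$k), "-", row$k), row$rmsep, row$r2))
}
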