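#' Random fold assignment
#'
#' Random partition of `n` items into `n_folds` folds whose sizes differ by
#' at most one; deterministic given `seed`.
#'
#' @param n Number of items.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
assign_folds <- function(n, n_folds = 10, seed = 1L) {
  if (n_folds < 2) abort("n_folds must be >= 2.")
  if (n < n_folds) abort("Need n >= n_folds.")
  withr::with_seed(child_seed(seed, 5),
    sample(rep(seq_len(n_folds), length.out = n)))
}

#' Root mean squared error of prediction
#'
#' `sqrt(mean((observed - predicted)^2))`, on whatever scale the inputs are
#' (the package computes it on the sqrt modeling scale by default).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
rmsep <- function(observed, predicted) {
  if (length(observed) != length(predicted)) abort("Length mismatch.")
  if (length(observed) < 1) abort("Need at least one observation.")
  sqrt(mean((observed - predicted)^2))
}

#' Cross-validated R-squared
#'
#' `1 - MSE(predicted) / var(observed)`, floored at zero; the variance uses
#' the `n` denominator so that `cv_r2 = 1 - rmsep^2 / var(observed)` holds
#' exactly whenever no flooring occurs. Predictions worse than the constant
#' mean predictor therefore score 0, not negative.
#'
#' @inheritParams rmsep
#' @return Scalar in `[0, 1]`.
#' @export
cv_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted)) abort("Length mismatch.")
  v <- mean((observed - mean(observed))^2)
  if (v == 0) abort("Constant observations: R2 undefined.")
  max(0, 1 - mean((observed - predicted)^2) / v)
}

#' 10-fold cross-validation of the exposure prediction methods
#'
#' For each fold, covariate pre-processing statistics, PLS weights and
#' kriging parameters are all re-estimated on the training monitors only
#' (strict no-leakage), and held-out predictions are assembled over all
#' folds. One result row is produced per (method, k) combination;
#' `nearest_monitor` does not depend on `k` and appears once with `k = NA`.
#'
#' @param study A [simulate_study()] object, or a list with `monitors`
#'   (id, x, y, conc_sqrt) and `covariates_monitors` (id + raw covariates).
#' @param methods Subset of `c("pls_only", "pls_uk", "nearest_monitor")`.
#' @param k_grid PLS component counts to evaluate (default `1:10`).
#' @param n_folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param family Variogram family for the `pls_uk` method.
#' @param prep_args Extra arguments to [prep_covariates()].
#' @return A tibble of class `cv_results`: `method`, `k`, `rmsep`, `r2`, and
#'   a `predictions` list-column of per-monitor held-out tibbles
#'   (id, fold, observed, predicted).
#' @export
cross_validate <- function(study,
                           methods = c("pls_only", "pls_uk", "nearest_monitor"),
                           k_grid = 1:10, n_folds = 10, seed = 1L,
                           family = "exponential", prep_args = list()) {
  methods <- match.arg(methods, several.ok = TRUE)
  mon <- study$monitors
  covs <- study$covariates_monitors
  n <- nrow(mon)
  k_grid <- sort(unique(as.integer(k_grid)))
  folds <- assign_folds(n, n_folds, seed)
  coords <- as_coord_matrix(mon)
  y <- mon$conc_sqrt

  need_k <- intersect(methods, c("pls_only", "pls_uk"))
  preds <- list()
  add_pred <- function(method, k, idx, fold, p) {
    key <- paste(method, k, sep = "|")
    preds[[key]] <<- bind_rows(preds[[key]], tibble(
      id = mon$id[idx], fold = fold, observed = y[idx], predicted = p))
  }

  for (f in seq_len(n_folds)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if ("nearest_monitor" %in% methods) {
      p <- nearest_monitor(coords[tr, , drop = FALSE], y[tr],
        coords[te, , drop = FALSE], ids_obs = mon$id[tr])$pred_sqrt
      add_pred("nearest_monitor", NA_integer_, te, f, p)
    }
    if (length(need_k) > 0) {
      prep <- do.call(prep_covariates, c(list(covs[tr, , drop = FALSE]), prep_args))
      cov_te <- apply_prep(prep, covs[te, , drop = FALSE])
      for (k in k_grid) {
        pls <- fit_pls(prep$table, y[tr], k)
        if ("pls_only" %in% methods) {
          add_pred("pls_only", k, te, f,
            predict_pls_only(pls, cov_te)$pred_sqrt)
        }
        if ("pls_uk" %in% methods) {
          sc_tr <- pls$scores
          sc_te <- project_scores(pls, cov_te)
          kf <- tryCatch(
            fit_universal_kriging(sc_tr, y[tr], coords[tr, , drop = FALSE],
              family = family, hessian = FALSE),
            error = function(e) e
          )
          if (inherits(kf, "error")) {
            inform(sprintf("Fold %d, k = %d: kriging retry with extra starts.", f, k))
            kf <- tryCatch(
              fit_universal_kriging(sc_tr, y[tr], coords[tr, , drop = FALSE],
                family = family, hessian = FALSE, n_starts = 9),
              error = function(e) abort(sprintf(
                "Kriging failed in fold %d (k = %d): %s", f, k, conditionMessage(e)))
            )
          }
          add_pred("pls_uk", k, te, f,
            predict_uk(kf, sc_te, coords[te, , drop = FALSE])$pred_sqrt)
        }
      }
    }
  }

  out <- purrr::imap(preds, function(tb, key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    tb <- arrange(tb, .data$id)
    tibble(
      method = parts[1],
      k = suppressWarnings(as.integer(parts[2])),
      rmsep = rmsep(tb$observed, tb$predicted),
      r2 = cv_r2(tb$observed, tb$predicted),
      predictions = list(tb)
    )
  }) %>% bind_rows() %>% arrange(.data$method, .data$k)
  attr(out, "fold_assignment") <- folds
  attr(out, "seed") <- seed
  class(out) <- c("cv_results", class(tibble()))
  out
}

#' Select the best prediction model from CV results
#'
#' Returns the (method, k) with the smallest RMSEP; ties are broken by the
#' smaller k, then by method order `pls_only`, `pls_uk`, `nearest_monitor`.
#'
#' @param cv_results A [cross_validate()] result (or any tibble with
#'   `method`, `k`, `rmsep`, `r2` columns).
#' @return One-row tibble with the selected `method`, `k`, `rmsep`, `r2`.
#' @export
select_model <- function(cv_results) {
  if (nrow(cv_results) < 1) abort("No CV results to select from.")
  rank_m <- match(cv_results$method, c("pls_only", "pls_uk", "nearest_monitor"))
  k_ord <- ifelse(is.na(cv_results$k), Inf, cv_results$k)
  ord <- order(cv_results$rmsep, k_ord, rank_m)
  dplyr::select(as_tibble(cv_results)[ord[1], ], dplyr::all_of(c("method", "k", "rmsep", "r2")))
}

#' @export
tidy.cv_results <- function(x, ...) {
  dplyr::select(as_tibble(x), -dplyr::any_of("predictions"))
}

#' @export
print.cv_results <- function(x, ...) {
  cat("Cross-validation results (", length(attr(x, "fold_assignment")),
    " monitors)\n", sep = "")
  print(tidy(x))
  invisible(x)
}
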