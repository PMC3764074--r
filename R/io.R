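# CSV input/output and the end-to-end pipeline.

read_checked <- function(path, required) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0(basename(path), " lacks required column(s): ",
      paste(missing, collapse = ", ")))
  }
  tab
}

#' Read monitor, covariate and subject tables
#'
#' `read_monitors()` expects columns `id, x, y` and either `conc` (raw
#' concentration, sqrt-transformed on load) or `conc_sqrt`; negative
#' concentrations, duplicate ids and duplicate coordinates are rejected.
#' `read_covariates()` expects `id` plus numeric covariate columns.
#' `read_subjects()` expects `id, x, y, y_outcome` plus optional `z_*`
#' adjustment columns.
#'
#' @param path CSV path. Lines starting with `#` are treated as comments.
#' @return A validated tibble.
#' @export
read_monitors <- function(path) {
  tab <- read_checked(path, c("id", "x", "y"))
  if (!any(c("conc", "conc_sqrt") %in% names(tab))) {
    abort("monitors file needs a conc or conc_sqrt column.")
  }
  if (anyDuplicated(tab$id)) abort("Duplicate monitor ids.")
  if (anyDuplicated(tab[c("x", "y")])) abort("Duplicate monitor coordinates.")
  if ("conc" %in% names(tab)) {
    if (any(tab$conc < 0)) abort("Negative concentrations.")
    tab$conc_raw <- tab$conc
    tab$conc_sqrt <- sqrt(tab$conc)
    tab$conc <- NULL
  } else {
    if (any(tab$conc_sqrt < 0)) abort("Negative sqrt-scale concentrations.")
    tab$conc_raw <- tab$conc_sqrt^2
  }
  num <- c("x", "y", "conc_sqrt", "conc_raw")
  if (!all(purrr::map_lgl(tab[num], is.numeric))) abort("Non-numeric monitor columns.")
  tab
}

#' @rdname read_monitors
#' @export
read_covariates <- function(path) {
  tab <- read_checked(path, "id")
  if (anyDuplicated(tab$id)) abort("Duplicate location ids.")
  if (ncol(tab) < 2) abort("Covariate file has no covariate columns.")
  if (!all(purrr::map_lgl(tab[-1], is.numeric))) abort("Non-numeric covariate columns.")
  tab
}

#' @rdname read_monitors
#' @export
read_subjects <- function(path) {
  tab <- read_checked(path, c("id", "x", "y", "y_outcome"))
  if (anyDuplicated(tab$id)) abort("Duplicate subject ids.")
  if (!all(purrr::map_lgl(tab[-1], is.numeric))) abort("Non-numeric subject columns.")
  tab
}

#' Write a synthetic study to CSV files
#'
#' Writes `monitors.csv` (id, x, y, conc_sqrt), `covariates.csv` (monitor and
#' subject covariates stacked, with a `site` column), `subjects.csv`
#' (id, x, y, y_outcome, z_*) and `config.yaml` capturing every scenario
#' field, into `dir`.
#'
#' @param study A [simulate_study()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$monitors[c("id", "x", "y", "conc_sqrt")],
    file.path(dir, "monitors.csv"))
  covs <- bind_rows(
    mutate(study$covariates_monitors, site = "monitor", .after = "id"),
    mutate(study$covariates_subjects, site = "subject", .after = "id")
  )
  readr::write_csv(covs, file.path(dir, "covariates.csv"))
  sub <- dplyr::select(study$subjects, -dplyr::any_of(c("true_sqrt", "true_raw")))
  readr::write_csv(sub, file.path(dir, "subjects.csv"))
  cfg <- unclass(study$config)
  cfg$theta_true <- as.numeric(cfg$theta_true)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory containing `monitors.csv`, `covariates.csv`,
#'   `subjects.csv`.
#' @return A list shaped like a study (without ground truth).
#' @export
read_study <- function(dir) {
  monitors <- read_monitors(file.path(dir, "monitors.csv"))
  covs <- read_checked(file.path(dir, "covariates.csv"), c("id", "site"))
  subjects <- read_subjects(file.path(dir, "subjects.csv"))
  list(
    monitors = monitors,
    covariates_monitors = dplyr::select(filter(covs, .data$site == "monitor"), -"site"),
    subjects = subjects,
    covariates_subjects = dplyr::select(filter(covs, .data$site == "subject"), -"site")
  )
}

#' Run the full two-stage pipeline
#'
#' Orchestrates the whole analysis on a study: covariate pre-processing,
#' cross-validated model selection over PLS component counts and prediction
#' methods, the final exposure fit, subject prediction, the naive health
#' fit, and parameter-bootstrap measurement-error correction at
#' `lambda = 0` and `lambda = 1` (plus optional SIMEX). All randomness flows
#' from `seed`, split per stage. If `output_dir` is given, every result
#' table is written as CSV (stamped with a configuration hash) along with a
#' plain-text provenance log.
#'
#' @param study A study (from [simulate_study()] or [read_study()]).
#' @param k_grid PLS component counts to cross-validate.
#' @param n_folds CV folds.
#' @param family Variogram family.
#' @param B Bootstrap replicates.
#' @param simex Also run SIMEX bias extrapolation.
#' @param seed Root seed.
#' @param z_names Names of adjustment-covariate columns in
#'   `study$subjects` (default: all columns starting with `"z_"`).
#' @param prep_args Extra arguments to [prep_covariates()].
#' @param output_dir Optional directory for CSV artifacts and the log.
#' @return List of class `pipeline_result`: `cv`, `selected`, `exposure_fit`,
#'   `predictions`, `health_naive`, `pb0`, `pb1`, `simex` (or `NULL`),
#'   `results` (a Table-5-shaped coefficient tibble).
#' @export
run_pipeline <- function(study, k_grid = 1:5, n_folds = 10,
                         family = "exponential", B = 500, simex = FALSE,
                         seed = 1L, z_names = NULL, prep_args = list(),
                         output_dir = NULL) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    inform(msg)
  }
  say("stage 1/5: cross-validation (%d folds, k in {%s})", n_folds,
    paste(k_grid, collapse = ","))
  cv <- cross_validate(study, k_grid = k_grid, n_folds = n_folds,
    seed = child_seed(seed, 101), family = family, prep_args = prep_args)
  sel <- select_model(filter(cv, .data$method != "nearest_monitor"))
  say("selected: %s with k = %d (RMSEP %.4g, R2 %.3f)", sel$method, sel$k,
    sel$rmsep, sel$r2)

  say("stage 2/5: final exposure fit")
  efit <- fit_exposure(study, k = sel$k, family = family, prep_args = prep_args)

  say("stage 3/5: subject exposure prediction (%s)", sel$method)
  pred <- predict_subjects(efit,
    method = if (sel$method == "pls_only") "pls_only" else "pls_uk",
    ids = study$subjects$id)

  if (is.null(z_names)) z_names <- grep("^z_", names(study$subjects), value = TRUE)
  say("stage 4/5: naive health model (%d adjustment covariates)", length(z_names))
  hfit <- fit_health_ols(study$subjects$y_outcome, pred$pred_raw,
    if (length(z_names)) study$subjects[z_names] else NULL)

  say("stage 5/5: parameter bootstrap (B = %d)", B)
  pb0 <- partial_parametric_bootstrap(study, efit, hfit,
    bootstrap_config(B = B, seed = child_seed(seed, 202)))
  pb1 <- parameter_bootstrap(study, efit, hfit,
    bootstrap_config(B = B, lambda = 1, seed = child_seed(seed, 202)))
  sx <- NULL
  if (isTRUE(simex)) {
    say("extra: SIMEX bias extrapolation")
    sx <- simex_bias(study, efit, hfit,
      bootstrap_config(B = B, seed = child_seed(seed, 202)))
  }

  res <- bind_rows(
    tibble(method = "naive", beta = hfit$beta_x, se = hfit$se_naive[["w"]]),
    tibble(method = "pb_lambda0", beta = pb0$beta_corrected, se = pb0$se_boot),
    tibble(method = "pb_lambda1", beta = pb1$beta_corrected, se = pb1$se_boot),
    if (!is.null(sx)) tibble(method = "simex", beta = sx$beta_corrected,
      se = pb1$se_boot)
  )
  ci <- normal_ci(res$beta, res$se)
  res$ci_lo <- ci[, 1]; res$ci_hi <- ci[, 2]

  out <- structure(list(cv = cv, selected = sel, exposure_fit = efit,
    predictions = pred, health_naive = hfit, pb0 = pb0, pb1 = pb1,
    simex = sx, results = res, seed = seed), class = "pipeline_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    hash <- rlang::hash(list(k_grid, n_folds, family, B, seed, z_names))
    stamp <- function(path, tab) {
      writeLines(paste0("# plskrige config ", hash), path)
      readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
    }
    stamp(file.path(output_dir, "cv.csv"), tidy(cv))
    stamp(file.path(output_dir, "predictions.csv"),
      dplyr::select(pred, -dplyr::any_of("pred_var")))
    stamp(file.path(output_dir, "health_naive.csv"), hfit$coefficients)
    stamp(file.path(output_dir, "results.csv"), res)
    writeLines(c(paste0("# plskrige run, config ", hash), log_lines),
      file.path(output_dir, "run.log"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Two-stage pipeline result\n")
  cat("  selected exposure model:", x$selected$method, "k =", x$selected$k, "\n")
  print(x$results)
  invisible(x)
}
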