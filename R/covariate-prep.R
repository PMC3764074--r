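# Geographic-covariate screening and standardization that precedes PLS.
# Pipeline order is fixed: homogeneity screen -> outlier screen -> compile
# minimum-distance variables -> re-screen compiled -> log/truncate distances
# -> standardize.

#' Drop near-homogeneous covariates
#'
#' Removes every covariate whose single most frequent value occurs in
#' strictly more than `threshold` of the rows (default 85%). Constant columns
#' are always dropped.
#'
#' @param table Covariate tibble (an `id` column, if present, is kept aside).
#' @param threshold Proportion in `(0, 1]`.
#' @return List with the filtered `table` and `dropped` column names.
#' @export
drop_homogeneous <- function(table, threshold = 0.85) {
  cols <- setdiff(names(table), "id")
  if (length(cols) == 0) abort("Covariate table has no covariate columns.")
  frac <- purrr::map_dbl(table[cols], ~ max(table(.x)) / length(.x))
  dropped <- cols[frac > threshold]
  if (length(dropped) == length(cols)) {
    warn("All covariates dropped by the homogeneity screen.")
  }
  list(table = dplyr::select(table, -dplyr::all_of(dropped)), dropped = dropped)
}

#' Drop outlier-prone covariates
#'
#' Removes covariates whose most extreme standardized value exceeds `cutoff`
#' in absolute value: `max |(x - mean)/sd| > cutoff` (default 7).
#'
#' @inheritParams drop_homogeneous
#' @param cutoff Z-score cutoff; `Inf` disables the screen.
#' @return List with the filtered `table` and `dropped` names.
#' @export
drop_outlier_prone <- function(table, cutoff = 7) {
  cols <- setdiff(names(table), "id")
  zmax <- purrr::map_dbl(table[cols], function(x) {
    s <- sd(x)
    if (s == 0) return(0)
    max(abs((x - mean(x)) / s))
  })
  dropped <- cols[zmax > cutoff]
  list(table = dplyr::select(table, -dplyr::all_of(dropped)), dropped = dropped)
}

#' Log-transform and truncate distance covariates
#'
#' Each distance value `d` (km) becomes `log(min(d, cap))`. Distances are
#' floored at `floor_km` (default 1 m) before the log, so zero distances are
#' representable; genuinely negative distances are an error.
#'
#' @inheritParams drop_homogeneous
#' @param distance_columns Names of distance-type columns.
#' @param cap Truncation cap in km (default 10; 25 is the other documented
#'   convention).
#' @param log_base `exp(1)` (default) or `10`.
#' @param floor_km Lower floor in km applied before the log.
#' @return The table with distance columns transformed.
#' @export
transform_distances <- function(table, distance_columns, cap = 10,
                                log_base = exp(1), floor_km = 0.001) {
  for (cl in distance_columns) {
    if (!cl %in% names(table)) abort(paste0("Unknown distance column: ", cl))
    d <- pmax(table[[cl]], floor_km)
    if (any(d <= 0)) abort(paste0("Non-positive distances in column ", cl))
    table[[cl]] <- log(pmin(d, cap), base = log_base)
  }
  table
}

#' Compile minimum-distance covariates
#'
#' For each named group of raw (pre-log) distance columns, adds a column with
#' the row-wise minimum distance over the group, e.g. minimum distance to any
#' major road. Compiled columns are then subject to the same inclusion
#' screens as the originals (done by [prep_covariates()]).
#'
#' @inheritParams drop_homogeneous
#' @param groups Named list of character vectors of member column names.
#' @return The table with one `min_<group>` column appended per group.
#' @export
compile_min_distances <- function(table, groups) {
  for (g in names(groups)) {
    members <- groups[[g]]
    if (length(members) == 0) abort(paste0("Empty compile group: ", g))
    missing <- setdiff(members, names(table))
    if (length(missing) > 0) {
      abort(paste0("Compile group ", g, " references unknown columns: ",
        paste(missing, collapse = ", ")))
    }
    table[[paste0("min_", g)]] <- do.call(pmin, table[members])
  }
  table
}

#' Mean-center and scale covariates
#'
#' Centers each column at its mean and scales by its sample SD (n - 1
#' denominator). The stored centers/scales are applied verbatim to covariates
#' at new locations, so a standardized subject table generally does *not*
#' have mean zero.
#'
#' @inheritParams drop_homogeneous
#' @return List with the standardized `table`, `centers`, `scales`.
#' @export
standardize_covariates <- function(table) {
  cols <- setdiff(names(table), "id")
  centers <- purrr::map_dbl(table[cols], mean)
  scales <- purrr::map_dbl(table[cols], sd)
  if (any(scales == 0)) {
    abort(paste0("Zero-SD columns cannot be standardized: ",
      paste(cols[scales == 0], collapse = ", ")))
  }
  for (cl in cols) table[[cl]] <- (table[[cl]] - centers[[cl]]) / scales[[cl]]
  list(table = table, centers = centers, scales = scales)
}

#' Run the full covariate pre-processing pipeline
#'
#' Applies, in order: the homogeneity screen, the outlier screen, compilation
#' of minimum-distance variables, the same two screens on the compiled
#' columns, log/truncation of all surviving distance-type columns, and
#' standardization. Returns the processed table together with a `prep_report`
#' recording every decision, so the identical transformation can be applied
#' to covariates at subject locations with [apply_prep()].
#'
#' @param table Covariate tibble; may contain an `id` column.
#' @param distance_columns Names of distance-type columns. `NULL` (default)
#'   auto-detects columns whose names start with `"dist"`.
#' @param groups Named list of compile groups (members are raw distance
#'   columns), or `NULL`.
#' @param homog_threshold,outlier_cutoff,cap,log_base,floor_km Screen and
#'   transform settings; see the individual steps.
#' @return Object of class `covariate_prep`: `table` (standardized tibble)
#'   and `report` (dropped/transformed/compiled names, centers, scales,
#'   settings).
#' @export
prep_covariates <- function(table, distance_columns = NULL, groups = NULL,
                            homog_threshold = 0.85, outlier_cutoff = 7,
                            cap = 10, log_base = exp(1), floor_km = 0.001) {
  table <- as_tibble(table)
  if (nrow(table) == 0) abort("Empty covariate table.")
  if (is.null(distance_columns)) {
    distance_columns <- grep("^dist", names(table), value = TRUE)
  }
  s1 <- drop_homogeneous(table, homog_threshold)
  s2 <- drop_outlier_prone(s1$table, outlier_cutoff)
  tab <- s2$table

  compiled <- character(0)
  if (!is.null(groups) && length(groups) > 0) {
    # compile from raw distances still present in the input table
    raw <- dplyr::select(table, dplyr::any_of(unique(c("id", unlist(groups)))))
    comp <- compile_min_distances(raw, groups)
    new_cols <- setdiff(names(comp), names(raw))
    ctab <- comp[new_cols]
    c1 <- drop_homogeneous(ctab, homog_threshold)
    c2 <- if (ncol(c1$table) > 0) drop_outlier_prone(c1$table, outlier_cutoff) else
      list(table = c1$table, dropped = character(0))
    compiled <- names(c2$table)
    tab <- bind_cols(tab, c2$table)
    s1$dropped <- c(s1$dropped, c1$dropped)
    s2$dropped <- c(s2$dropped, c2$dropped)
  }

  dist_cols <- intersect(c(distance_columns, compiled), names(tab))
  tab <- transform_distances(tab, dist_cols, cap = cap, log_base = log_base,
    floor_km = floor_km)
  s3 <- standardize_covariates(tab)

  report <- structure(list(
    dropped_homogeneous = s1$dropped,
    dropped_outlier = s2$dropped,
    transformed_distance = dist_cols,
    compiled = compiled,
    groups = groups,
    centers = s3$centers,
    scales = s3$scales,
    settings = list(homog_threshold = homog_threshold,
      outlier_cutoff = outlier_cutoff, cap = cap, log_base = log_base,
      floor_km = floor_km)
  ), class = "prep_report")

  structure(list(table = s3$table, report = report), class = "covariate_prep")
}

#' Apply a fitted pre-processing pipeline to new covariates
#'
#' Reuses the drop decisions, compiled groups, distance transform and
#' monitor-fit centers/scales of a [prep_covariates()] object on covariates
#' at new (e.g. subject) locations.
#'
#' @param prep A `covariate_prep` object.
#' @param table New covariate tibble with the same raw columns as the
#'   training table.
#' @return Standardized tibble with the same columns as `prep$table`.
#' @export
apply_prep <- function(prep, table) {
  stopifnot(inherits(prep, "covariate_prep"))
  rep <- prep$report
  table <- as_tibble(table)
  if (!is.null(rep$groups) && length(rep$groups) > 0) {
    table <- compile_min_distances(table, rep$groups)
  }
  keep <- setdiff(names(prep$table), "id")
  missing <- setdiff(keep, names(table))
  if (length(missing) > 0) {
    abort(paste0("New table lacks required columns: ", paste(missing, collapse = ", ")))
  }
  out <- dplyr::select(table, dplyr::any_of(c("id", keep)))
  st <- rep$settings
  out <- transform_distances(out, intersect(rep$transformed_distance, keep),
    cap = st$cap, log_base = st$log_base, floor_km = st$floor_km)
  for (cl in keep) out[[cl]] <- (out[[cl]] - rep$centers[[cl]]) / rep$scales[[cl]]
  out
}

#' @export
print.prep_report <- function(x, ...) {
  cat("Covariate pre-processing report\n")
  cat("  dropped (homogeneity):", length(x$dropped_homogeneous), "\n")
  cat("  dropped (outlier):    ", length(x$dropped_outlier), "\n")
  cat("  compiled columns:     ", length(x$compiled), "\n")
  cat("  distance-transformed: ", length(x$transformed_distance),
    sprintf(" (cap %.3g km, log base %.3g)\n", x$settings$cap, x$settings$log_base))
  cat("  covariates retained:  ", length(x$centers), "\n")
  invisible(x)
}

#' @export
print.covariate_prep <- function(x, ...) {
  print(x$report)
  invisible(x)
}
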