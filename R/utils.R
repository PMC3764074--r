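# Internal numerical helpers shared across modules.

# Euclidean distance matrix between two coordinate sets (n x 2 matrices, km).
dist_matrix <- function(a, b = NULL) {
  a <- as.matrix(a)
  if (is.null(b)) {
    as.matrix(stats::dist(a))
  } else {
    b <- as.matrix(b)
    dx <- outer(a[, 1], b[, 1], "-")
    dy <- outer(a[, 2], b[, 2], "-")
    sqrt(dx^2 + dy^2)
  }
}

# Cholesky with diagonal jitter escalation; errors after `tries` attempts.
# Returns the upper-triangular factor U with crossprod(U) = S (+ jitter).
chol_jitter <- function(S, tries = 4L, start = 1e-10) {
  U <- tryCatch(chol(S), error = function(e) NULL)
  jit <- start * mean(diag(S))
  k <- 0L
  while (is.null(U) && k < tries) {
    U <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    jit <- jit * 100
    k <- k + 1L
  }
  if (is.null(U)) {
    abort("Covariance matrix is not positive definite even after jitter.")
  }
  U
}

# Project a symmetric matrix onto the nearest (in Frobenius sense) PSD matrix
# by clipping negative eigenvalues at zero.
nearest_psd <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= 0)) return(S)
  v <- pmax(e$values, 0)
  S2 <- e$vectors %*% (v * t(e$vectors))
  (S2 + t(S2)) / 2
}

# Coordinates as an n x 2 numeric matrix from a tibble with x/y columns or a
# two-column matrix.
as_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    stopifnot(all(c("x", "y") %in% names(coords)))
    coords <- cbind(coords$x, coords$y)
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || !is.numeric(coords)) {
    abort("Coordinates must be an n x 2 numeric matrix or a data frame with x, y columns.")
  }
  coords
}

# Numeric covariate matrix from a tibble (dropping an id column if present).
as_cov_matrix <- function(table) {
  if (is.data.frame(table)) {
    table <- dplyr::select(table, -dplyr::any_of("id"))
    m <- as.matrix(table)
  } else {
    m <- as.matrix(table)
  }
  if (!is.numeric(m)) abort("Covariate table must be all numeric.")
  m
}

# Derive a child seed from a root seed; stays inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587) + 1L
}
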