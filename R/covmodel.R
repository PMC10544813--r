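# Data containers and the marginal-CDF problem for the spatial probit model.
#
# The marginal likelihood of a binary response vector Y under
#   Y(s_i) = I(Z_i <= x(s_i)'beta + w(s_i)),  w ~ GP(0, C(.,.|theta))
# is the multivariate normal CDF Phi_n(m, Sigma) with
#   m = D X beta,  Sigma = I_n + D C(theta) D,  D = diag(2Y - 1).
# Sigma is never materialized densely on the main path: `sigma_block()`
# evaluates arbitrary sub-blocks on demand.

#' Point-referenced binary spatial data
#'
#' Bundles 2-D coordinates, a 0/1 response and an optional covariate matrix
#' into a validated dataset. Coordinates may be on the unit square or in raw
#' units; distances are Euclidean. Duplicate coordinates are rejected (they
#' make the sequential conditioning singular) rather than jittered.
#'
#' @param coords numeric matrix with `n` rows and 2 columns.
#' @param y length-`n` vector with entries exactly 0 or 1 (e.g. species
#'   absence/presence).
#' @param X optional `n x p` covariate matrix; `NULL` means no covariates.
#' @return An object of class `spatial_dataset` with elements `coords`, `y`
#'   and `X` (an `n x 0` matrix when there are no covariates).
#' @examples
#' d <- spatial_dataset(cbind(c(0, 1, 0.5), c(0, 0, 1)), c(1, 0, 1))
#' d
#' @export
spatial_dataset <- function(coords, y, X = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("`coords` must have exactly two columns")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("`coords` must be finite")
  n <- nrow(coords)
  if (n < 1L)
    stop("at least one location is required")
  y <- as.numeric(y)
  if (length(y) != n)
    stop(sprintf("length of `y` (%d) does not match the number of locations (%d)",
                 length(y), n))
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("`y` must contain only 0 or 1; invalid at row(s) %s",
                 paste(head(bad, 5L), collapse = ", ")))
  if (anyDuplicated(coords)) {
    dup <- which(duplicated(coords))
    stop(sprintf("duplicate coordinates are not allowed; offending row(s) %s",
                 paste(head(dup, 5L), collapse = ", ")))
  }
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0L)
  } else {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (nrow(X) != n)
      stop(sprintf("`X` has %d rows but there are %d locations", nrow(X), n))
    if (!all(is.finite(X)))
      stop("`X` must be finite")
  }
  structure(list(coords = unname(coords), y = y, X = unname(X)),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d locations, %d covariate(s), %.0f%% ones\n",
              nrow(x$coords), ncol(x$X), 100 * mean(x$y)))
  invisible(x)
}

#' Spatial probit model parameters
#'
#' Fixed-effect coefficients together with the exponential-kernel
#' hyper-parameters theta = (sigma2, phi): `sigma2` is the spatial variance
#' and `phi` the spatial decay (larger `phi` means shorter-range
#' correlation).
#'
#' @param beta numeric fixed-effect vector (length 0 for an intercept-free,
#'   covariate-free model).
#' @param sigma2 positive spatial variance.
#' @param phi positive spatial decay.
#' @return An object of class `probit_params`.
#' @export
probit_params <- function(beta = numeric(0), sigma2, phi) {
  beta <- as.numeric(beta)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0)
    stop("`sigma2` must be a positive finite scalar")
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("`phi` must be a positive finite scalar")
  structure(list(beta = beta, sigma2 = as.numeric(sigma2),
                 phi = as.numeric(phi)),
            class = "probit_params")
}

#' @export
print.probit_params <- function(x, ...) {
  cat(sprintf("probit_params: sigma2 = %g, phi = %g, %d fixed effect(s)\n",
              x$sigma2, x$phi, length(x$beta)))
  invisible(x)
}

#' Exponential covariance kernel
#'
#' Evaluates `C(s_i, s_j) = sigma2 * exp(-phi * ||s_i - s_j||)` between two
#' sets of 2-D locations (Euclidean distance).
#'
#' @param coords_a,coords_b matrices of 2-D coordinates (rows are points);
#'   `coords_b` defaults to `coords_a`.
#' @param sigma2,phi positive kernel parameters.
#' @return The `nrow(coords_a) x nrow(coords_b)` covariance matrix.
#' @examples
#' exponential_covariance(rbind(c(0, 0)), rbind(c(0.1, 0)), 1, 30)  # exp(-3)
#' @export
exponential_covariance <- function(coords_a, coords_b = coords_a, sigma2, phi) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0)
    stop("`sigma2` must be a positive finite scalar")
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("`phi` must be a positive finite scalar")
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (ncol(a) != 2L || ncol(b) != 2L)
    stop("coordinates must be 2-D")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("coordinates must be finite")
  d <- sqrt(outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2)
  sigma2 * exp(-phi * d)
}

#' Marginal-CDF problem for a binary spatial dataset
#'
#' Builds the mean vector `m = D X beta` and the implicit covariance
#' `Sigma = I_n + D C(theta) D` (with `D = diag(2y - 1)`) whose CDF at `m`
#' is the marginal likelihood of the observed labels. `Sigma` is exposed
#' through on-demand block evaluation (see [sigma_block()]) because dense
#' storage is the binding constraint at large `n`.
#'
#' @param dataset a [spatial_dataset()].
#' @param params a [probit_params()]; `length(beta)` must equal `ncol(X)`.
#' @return An object of class `marginal_problem` with elements `m`, `sign`
#'   (the diagonal of `D`), `coords` and `params`.
#' @export
marginal_problem <- function(dataset, params) {
  stopifnot(inherits(dataset, "spatial_dataset"),
            inherits(params, "probit_params"))
  p <- length(params$beta)
  if (ncol(dataset$X) != p)
    stop(sprintf("`beta` has length %d but `X` has %d column(s)",
                 p, ncol(dataset$X)))
  n <- nrow(dataset$coords)
  sgn <- 2 * dataset$y - 1
  m <- if (p > 0L) sgn * drop(dataset$X %*% params$beta) else numeric(n)
  structure(list(m = m, sign = sgn, coords = dataset$coords,
                 params = params, n = n),
            class = "marginal_problem")
}

#' Evaluate a block of the marginal covariance on demand
#'
#' Returns `Sigma[rows, cols]` where `Sigma = I_n + D C D`; the identity
#' contribution is added wherever a row index equals a column index.
#'
#' @param problem a [marginal_problem()].
#' @param rows,cols integer index vectors.
#' @return A dense `length(rows) x length(cols)` matrix.
#' @export
sigma_block <- function(problem, rows, cols) {
  stopifnot(inherits(problem, "marginal_problem"))
  C <- exponential_covariance(problem$coords[rows, , drop = FALSE],
                              problem$coords[cols, , drop = FALSE],
                              problem$params$sigma2, problem$params$phi)
  S <- C * tcrossprod(problem$sign[rows], problem$sign[cols])
  S + outer(rows, cols, "==")
}
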