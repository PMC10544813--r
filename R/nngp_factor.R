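# NNGP (Vecchia) factorization of the marginal covariance Sigma = I + DCD:
# sum-of-coordinates ordering, nearest-predecessor neighbor sets, the sparse
# coefficient matrix A and conditional variances F with
# Sigma_tilde^{-1} = (I - A)' F^{-1} (I - A), recovery of the Cholesky
# columns of Sigma_tilde by forward substitution, and the O(n) extension of
# the factor for one prediction location.

#' Order locations by the sum of their coordinates
#'
#' Stable ascending sort on `x + y`; ties keep their original relative
#' order, so the permutation is deterministic.
#'
#' @param coords numeric matrix of 2-D coordinates.
#' @return An integer permutation of `1:nrow(coords)`.
#' @export
order_by_coordinate_sum <- function(coords) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("`coords` must be finite")
  order(coords[, 1L] + coords[, 2L])
}

#' Nearest-predecessor neighbor sets
#'
#' For locations already in their conditioning order, set `i` holds the
#' `min(m, i - 1)` predecessors closest in Euclidean distance (the first set
#' is empty). Distance ties are broken by the lower index, so the sets are
#' deterministic. The search is an exhaustive vectorized scan, which is
#' exact and fast at the sample sizes this package targets.
#'
#' @param ordered_coords coordinates in conditioning order.
#' @param m maximum number of neighbors (>= 1).
#' @return A list of `n` increasing integer vectors.
#' @export
build_neighbor_sets <- function(ordered_coords, m) {
  coords <- as.matrix(ordered_coords)
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("`m` must be a positive integer")
  m <- as.integer(m)
  n <- nrow(coords)
  out <- vector("list", n)
  out[[1L]] <- integer(0)
  x <- coords[, 1L]
  y <- coords[, 2L]
  for (i in seq_len(n)[-1L]) {
    pred <- seq_len(i - 1L)
    d2 <- (x[pred] - x[i])^2 + (y[pred] - y[i])^2
    k <- min(m, i - 1L)
    out[[i]] <- sort.int(order(d2)[seq_len(k)])
  }
  out
}

# row-wise flat (ptr/idx, 0-based) representation used by the C++ kernels
.flatten_neighbors <- function(neighbors) {
  list(ptr = as.integer(c(0L, cumsum(lengths(neighbors)))),
       idx = as.integer(unlist(neighbors)) - 1L)
}

#' Vecchia regression coefficients and conditional variances
#'
#' For each ordered location `i`, regresses dimension `i` of the marginal
#' covariance problem on its neighbor set: row `i` of `A` equals
#' `Sigma[i, N(i)] Sigma[N(i), N(i)]^{-1}` and
#' `f_i = Sigma_ii - A[i, N(i)] Sigma[N(i), i]`. Each row costs `O(m^3)`.
#'
#' @param problem a [marginal_problem()] whose coordinates are already in
#'   conditioning order.
#' @param neighbors neighbor sets from [build_neighbor_sets()].
#' @return An object of class `nngp_coefficients` with the sparse
#'   strictly-lower-triangular `A` (a `dgCMatrix`), the positive vector `F`,
#'   and the flat arrays used internally.
#' @export
nngp_coefficients <- function(problem, neighbors) {
  stopifnot(inherits(problem, "marginal_problem"))
  n <- problem$n
  if (length(neighbors) != n)
    stop("`neighbors` must have one entry per location")
  flat <- .flatten_neighbors(neighbors)
  res <- tryCatch(
    cpp_nngp_coefficients(problem$coords, problem$sign, flat$ptr, flat$idx,
                          problem$params$sigma2, problem$params$phi),
    error = function(e) stop("NNGP factorization failed: ",
                             conditionMessage(e), call. = FALSE))
  a_val <- drop(res$a_val)
  f <- drop(res$f)
  A <- Matrix::sparseMatrix(i = rep.int(seq_len(n), lengths(neighbors)),
                            j = as.integer(unlist(neighbors)),
                            x = a_val, dims = c(n, n))
  structure(list(A = A, F = f, ptr = flat$ptr, idx = flat$idx,
                 a_val = a_val, neighbors = neighbors),
            class = "nngp_coefficients")
}

#' Recover the NNGP Cholesky factor column by column
#'
#' Column `j` of the lower-triangular factor `L` (with `L L' = Sigma_tilde`)
#' solves the sparse triangular system `(I - A) l_j = sqrt(f_j) e_j` by
#' forward substitution, exploiting the at-most-`m` nonzeros per row of `A`
#' (`O(n)` per column, `O(n^2)` overall). Columns are independent, so they
#' may be computed in parallel; the result is identical for any worker
#' count because each column is a pure function of `(A, F)`.
#'
#' @param A an `nngp_coefficients` object, or a strictly-lower-triangular
#'   matrix (dense or `Matrix` sparse) of kriging coefficients.
#' @param F positive conditional variances (ignored when `A` is an
#'   `nngp_coefficients` object).
#' @param workers number of parallel workers for the column solves.
#' @return The dense `n x n` lower-triangular factor `L`.
#' @export
cholesky_columns <- function(A, F = NULL, workers = 1L) {
  if (inherits(A, "nngp_coefficients")) {
    ptr <- A$ptr; idx <- A$idx; a_val <- A$a_val; f <- A$F
  } else {
    f <- as.numeric(F)
    Am <- as(as(A, "CsparseMatrix"), "TsparseMatrix")
    ri <- Am@i + 1L
    ci <- Am@j + 1L
    xv <- Am@x
    if (any(ci >= ri)) stop("`A` must be strictly lower triangular")
    ord <- order(ri, ci)
    ri <- ri[ord]; ci <- ci[ord]; xv <- xv[ord]
    ptr <- as.integer(c(0L, cumsum(tabulate(ri, nbins = length(f)))))
    idx <- as.integer(ci) - 1L
    a_val <- xv
  }
  n <- length(f)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("`F` must be positive")
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || n < 2L * workers)
    return(cpp_chol_columns(ptr, idx, a_val, f, 0L, n - 1L))
  chunks <- split(seq_len(n), cut(seq_len(n), workers, labels = FALSE))
  blocks <- parallel::mclapply(chunks, function(jj)
    cpp_chol_columns(ptr, idx, a_val, f, jj[1L] - 1L, jj[length(jj)] - 1L),
    mc.cores = workers)
  do.call(cbind, blocks)
}

#' Build the full NNGP factor for a binary spatial dataset
#'
#' Convenience pipeline: order the locations by coordinate sum, build the
#' nearest-predecessor neighbor sets, compute the Vecchia coefficients of
#' `Sigma = I + DCD`, and materialize the Cholesky columns of the NNGP
#' covariance. All stored quantities live in ordered space; `order` maps
#' back to the original row indexing (`coords == dataset$coords[order, ]`).
#'
#' @param dataset a [spatial_dataset()].
#' @param params a [probit_params()].
#' @param m number of nearest neighbors (default 15).
#' @param workers parallel workers for the column solves.
#' @return An object of class `nngp_factor`.
#' @export
nngp_factor <- function(dataset, params, m = 15L, workers = 1L) {
  stopifnot(inherits(dataset, "spatial_dataset"),
            inherits(params, "probit_params"))
  ord <- order_by_coordinate_sum(dataset$coords)
  ds_o <- spatial_dataset(dataset$coords[ord, , drop = FALSE],
                          dataset$y[ord],
                          if (ncol(dataset$X)) dataset$X[ord, , drop = FALSE])
  problem <- marginal_problem(ds_o, params)
  neighbors <- build_neighbor_sets(ds_o$coords, m)
  coeffs <- nngp_coefficients(problem, neighbors)
  L <- cholesky_columns(coeffs, workers = workers)
  structure(list(order = ord, coords = ds_o$coords, y = ds_o$y,
                 sign = problem$sign, m_vec = problem$m,
                 neighbors = neighbors, A = coeffs$A, F = coeffs$F,
                 coeffs = coeffs, L = L, params = params,
                 m = as.integer(m), n = problem$n),
            class = "nngp_factor")
}

#' @export
print.nngp_factor <- function(x, ...) {
  cat(sprintf(paste0("nngp_factor: n = %d, m = %d neighbors, ",
                     "sigma2 = %g, phi = %g\n"),
              x$n, x$m, x$params$sigma2, x$params$phi))
  invisible(x)
}

#' Extend an NNGP factor by one prediction location
#'
#' Appends a new location as dimension `n + 1`: its neighbors are its `m`
#' nearest among *all* `n` training locations, the kriging weight vector
#' `a` and variance `f_new` come from the same conditional formulas as the
#' training rows (using `Sigma*` entries with the new location's sign), and
#' the bottom row of the extended factor is `v' = a' L` computed as a
#' sparse row product in `O(m n)`. Total added cost is `O(n)` in `n`.
#'
#' @param factor an [nngp_factor()].
#' @param new_coord length-2 numeric coordinate, distinct from all training
#'   locations.
#' @param new_sign +1 or -1; +1 encodes the event `Y(s_new) = 1`.
#' @param x_new optional covariate vector for the new location.
#' @return An object of class `extended_factor` with elements `neighbors`,
#'   `a`, `f_new`, `bottom_row` and `m_new`.
#' @export
extend_factor <- function(factor, new_coord, new_sign = 1, x_new = NULL) {
  stopifnot(inherits(factor, "nngp_factor"))
  new_coord <- as.numeric(new_coord)
  if (length(new_coord) != 2L || !all(is.finite(new_coord)))
    stop("`new_coord` must be a finite 2-D coordinate")
  if (!(new_sign %in% c(-1, 1)))
    stop("`new_sign` must be +1 or -1")
  s2 <- factor$params$sigma2
  phi <- factor$params$phi
  d2 <- (factor$coords[, 1L] - new_coord[1L])^2 +
        (factor$coords[, 2L] - new_coord[2L])^2
  if (any(d2 == 0))
    stop("prediction location coincides with a training location")
  k <- min(factor$m, factor$n)
  nb <- sort.int(order(d2)[seq_len(k)])
  cross <- s2 * exp(-phi * sqrt(d2[nb]))
  sv <- new_sign * factor$sign[nb] * cross
  Snn <- exponential_covariance(factor$coords[nb, , drop = FALSE],
                                factor$coords[nb, , drop = FALSE], s2, phi) *
         tcrossprod(factor$sign[nb])
  diag(Snn) <- 1 + s2
  a <- drop(solve(Snn, sv))
  f_new <- (1 + s2) - sum(a * sv)
  if (!(f_new > 0))
    stop("non-positive kriging variance at the prediction location")
  bottom_row <- drop(a %*% factor$L[nb, , drop = FALSE])
  beta <- factor$params$beta
  m_new <- if (length(beta)) {
    if (is.null(x_new))
      stop("`x_new` is required when the model has covariates")
    new_sign * sum(as.numeric(x_new) * beta)
  } else 0
  structure(list(neighbors = nb, a = a, f_new = f_new,
                 bottom_row = bottom_row, m_new = m_new,
                 new_sign = new_sign, new_coord = new_coord),
            class = "extended_factor")
}
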