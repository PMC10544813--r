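# Dense, slow, trusted reference implementations used in tests and
# small-n validation: the fully materialized marginal covariance, nested
# adaptive quadrature for low-dimensional normal CDFs, and dense-factor
# prediction. These provide the accuracy gold standard at desk scale; they
# do not scale and are never on the main path.

#' Dense marginal covariance Sigma = I + D C D
#'
#' Materializes the full matrix and checks positive definiteness via a
#' Cholesky factorization.
#'
#' @param dataset a [spatial_dataset()].
#' @param params a [probit_params()].
#' @return The dense symmetric `n x n` matrix.
#' @export
reference_dense_sigma <- function(dataset, params) {
  problem <- marginal_problem(dataset, params)
  n <- problem$n
  S <- sigma_block(problem, seq_len(n), seq_len(n))
  tryCatch(chol(S), error = function(e)
    stop("marginal covariance is not positive definite", call. = FALSE))
  S
}

#' High-accuracy normal CDF by nested adaptive quadrature (n <= 4)
#'
#' Triangularizes the integrand with a Cholesky factor and integrates the
#' sequential conditioning with nested calls to [stats::integrate()]. Used
#' as the independent oracle for the Monte-Carlo estimator at tiny `n`.
#'
#' @param m_vec CDF upper limits (length <= 4).
#' @param Sigma positive-definite covariance matrix.
#' @param rel_tol relative tolerance per 1-D integral.
#' @return The CDF value `Phi_n(m_vec, Sigma)`.
#' @examples
#' reference_quadrature_cdf(c(0, 0), rbind(c(1, 0.5), c(0.5, 1)))  # 1/3
#' @export
reference_quadrature_cdf <- function(m_vec, Sigma, rel_tol = 1e-8) {
  m_vec <- as.numeric(m_vec)
  n <- length(m_vec)
  if (n > 4L) stop("quadrature oracle supports n <= 4 only")
  Sigma <- as.matrix(Sigma)
  L <- t(chol(Sigma))
  rec <- function(k, zprev) {
    s <- if (k > 1L) sum(L[k, seq_len(k - 1L)] * zprev) else 0
    upper <- (m_vec[k] - s) / L[k, k]
    if (k == n) return(pnorm(upper))
    if (upper < -38) return(0)
    integrate(function(z)
        dnorm(z) * vapply(z, function(zi) rec(k + 1L, c(zprev, zi)), 0),
      lower = -Inf, upper = upper,
      rel.tol = rel_tol, abs.tol = 1e-12, subdivisions = 200L)$value
  }
  rec(1L, numeric(0))
}

#' Dense-factor reference predictions
#'
#' Identical pipeline to [predict_at_locations()] — same ordering, same
#' separation-of-variables estimator, same draw reuse — but with exact
#' dense Cholesky factors of `Sigma` and `Sigma*` instead of the NNGP
#' factor. Serves as the accuracy reference at small `n`.
#'
#' @param dataset a [spatial_dataset()].
#' @param params a [probit_params()].
#' @param test_coords `K x 2` matrix of prediction locations.
#' @param X_test optional covariates for the test locations.
#' @param R,seed,draws,clamp_eps as in [predict_at_locations()].
#' @return A `prediction_result` data frame.
#' @export
reference_full_predict <- function(dataset, params, test_coords,
                                   X_test = NULL, R = 10000L, seed = NULL,
                                   draws = NULL, clamp_eps = 1e-10) {
  stopifnot(inherits(dataset, "spatial_dataset"),
            inherits(params, "probit_params"))
  test_coords <- matrix(as.numeric(as.matrix(test_coords)), ncol = 2L)
  K <- nrow(test_coords)
  ord <- order_by_coordinate_sum(dataset$coords)
  ds_o <- spatial_dataset(dataset$coords[ord, , drop = FALSE],
                          dataset$y[ord],
                          if (ncol(dataset$X)) dataset$X[ord, , drop = FALSE])
  problem <- marginal_problem(ds_o, params)
  n <- problem$n
  S <- sigma_block(problem, seq_len(n), seq_len(n))
  L <- t(chol(S))
  if (is.null(draws)) draws <- sov_draws(n, R, seed)
  den <- estimate_log_cdf(problem$m, L, draws, clamp_eps, keep_z = TRUE)
  s2 <- params$sigma2
  prob <- rep(NA_real_, K)
  mc_se <- rep(NA_real_, K)
  status <- rep("ok", K)
  for (k in seq_len(K)) {
    d2 <- (ds_o$coords[, 1L] - test_coords[k, 1L])^2 +
          (ds_o$coords[, 2L] - test_coords[k, 2L])^2
    if (any(d2 == 0)) {
      status[k] <- "prediction location coincides with a training location"
      next
    }
    svec <- problem$sign * s2 * exp(-params$phi * sqrt(d2))
    v <- forwardsolve(L, svec)
    f_new <- (1 + s2) - sum(v^2)
    if (f_new <= 0) {
      status[k] <- "non-positive conditional variance"
      next
    }
    m_new <- if (length(params$beta)) {
      if (is.null(X_test))
        stop("`X_test` is required when the model has covariates")
      sum(as.numeric(X_test[k, ]) * params$beta)
    } else 0
    sc <- drop(den$z %*% v)
    log_e <- pnorm((m_new - sc) / sqrt(f_new), log.p = TRUE)
    r <- .ratio_estimate(den$per_sample_log_products + log_e,
                         den$per_sample_log_products)
    prob[k] <- r$prob
    mc_se[k] <- r$mc_se
  }
  out <- data.frame(index = seq_len(K), x = test_coords[, 1L],
                    y_coord = test_coords[, 2L], prob = prob, mc_se = mc_se,
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("prediction_result", "data.frame")
  out
}
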