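# Separation-of-variables (Genz) Monte-Carlo estimation of multivariate
# normal CDFs from a lower-triangular factor, and the prediction ratio
# Phi_{n+1}(m*, Sigma*_tilde) / Phi_n(m, Sigma_tilde) with shared draws.
#
# All per-draw products are kept in log space (the product of n e-terms
# underflows for n in the hundreds); the Monte-Carlo average is a
# log-mean-exp. The inner argument u_j e_j is clamped away from {0, 1}
# before the probit transform, since qnorm(0) = -Inf would poison the
# recursion.

#' Uniform draws for the separation-of-variables estimator
#'
#' An `R x n` matrix of i.i.d. U(0,1) variates from a single seeded
#' generator. The same draw object can (and for ratio estimation should) be
#' reused across numerator and denominator and across grid-search
#' likelihood evaluations: common random numbers reduce ratio variance and
#' smooth the likelihood surface.
#'
#' @param n dimension of the target CDF.
#' @param R number of Monte-Carlo samples (default 10000).
#' @param seed optional integer seed.
#' @return An object of class `sov_draws` with elements `u`, `R`, `n`,
#'   `seed`.
#' @export
sov_draws <- function(n, R = 10000L, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be a positive integer")
  if (!is.numeric(R) || R < 1) stop("`R` must be a positive integer")
  n <- as.integer(n)
  R <- as.integer(R)
  if (!is.null(seed)) set.seed(seed)
  structure(list(u = matrix(runif(R * n), R, n), R = R, n = n, seed = seed),
            class = "sov_draws")
}

#' Separation-of-variables terms for one draw
#'
#' Reference (pure R) evaluation of the recursion
#' `e_1 = Phi(m_1 / l_11)`,
#' `e_i = Phi((m_i - sum_{j<i} l_ij qnorm(u_j e_j)) / l_ii)`.
#' The vectorized C++ path used by [estimate_log_cdf()] implements the same
#' recursion; this scalar version exists for exposition and as an
#' independent cross-check in the tests.
#'
#' @param m_vec CDF upper limits.
#' @param L lower-triangular factor with positive diagonal.
#' @param u_row one row of uniforms, entries in (0, 1).
#' @param clamp_eps clamp for `u_j e_j` before the probit transform.
#' @return The length-`n` vector of e-terms, each in `[0, 1]`.
#' @export
sov_terms <- function(m_vec, L, u_row, clamp_eps = 1e-10) {
  n <- length(m_vec)
  L <- as.matrix(L)
  stopifnot(nrow(L) == n, ncol(L) == n, length(u_row) == n)
  e <- numeric(n)
  z <- numeric(n)
  for (i in seq_len(n)) {
    if (L[i, i] <= 0)
      stop("triangular factor has a non-positive diagonal entry")
    s <- if (i > 1L) sum(L[i, seq_len(i - 1L)] * z[seq_len(i - 1L)]) else 0
    e[i] <- pnorm((m_vec[i] - s) / L[i, i])
    z[i] <- qnorm(min(max(u_row[i] * e[i], clamp_eps), 1 - clamp_eps))
  }
  e
}

#' Monte-Carlo estimate of a multivariate normal log-CDF
#'
#' Estimates `log Phi_n(m, L L')` by averaging the per-draw products of the
#' separation-of-variables terms. Per-draw log-products are accumulated in
#' log space; the estimate is their log-mean-exp and the standard error is
#' propagated to the log scale by the delta method.
#'
#' @param m_vec CDF upper limits.
#' @param L lower-triangular factor of the covariance.
#' @param draws a [sov_draws()] object with `draws$n == length(m_vec)`.
#' @param clamp_eps clamp for `u_j e_j` before the probit transform.
#' @param keep_z keep the `R x n` matrix of probit-transformed conditioning
#'   variables (needed to reuse the draws in a prediction numerator).
#' @return An object of class `cdf_estimate` with `log_value`, `mc_se_log`,
#'   `per_sample_log_products`, and (optionally) `z`.
#' @export
estimate_log_cdf <- function(m_vec, L, draws, clamp_eps = 1e-10,
                             keep_z = FALSE) {
  stopifnot(inherits(draws, "sov_draws"))
  m_vec <- as.numeric(m_vec)
  L <- as.matrix(L)
  n <- length(m_vec)
  if (draws$n != n)
    stop(sprintf("draws are for dimension %d but the problem has dimension %d",
                 draws$n, n))
  if (any(diag(L) <= 0))
    stop("triangular factor has a non-positive diagonal entry")
  res <- cpp_sov(m_vec, t(L), draws$u, keep_z, clamp_eps)
  lp <- drop(res$logprod)
  if (!any(is.finite(lp)))
    stop("degenerate likelihood: every Monte-Carlo product underflowed to zero")
  M <- max(lp)
  w <- exp(lp - M)
  wbar <- mean(w)
  mc_se_log <- if (draws$R > 1L) sd(w) / (sqrt(draws$R) * wbar) else NA_real_
  structure(list(log_value = M + log(wbar), mc_se_log = mc_se_log,
                 per_sample_log_products = lp,
                 z = if (keep_z) res$z else NULL, R = draws$R),
            class = "cdf_estimate")
}

#' @export
print.cdf_estimate <- function(x, ...) {
  cat(sprintf("cdf_estimate: log value %.6f (mc se on log scale %.2g, R = %d)\n",
              x$log_value, x$mc_se_log, x$R))
  invisible(x)
}

# Ratio of two CDF estimates sharing their draws. Per-draw numerator
# products are <= the denominator products (the numerator appends one more
# e-term), so the ratio lies in [0, 1] by construction; the standard error
# accounts for the common-random-number covariance.
.ratio_estimate <- function(log_num, log_den) {
  Md <- max(log_den)
  a <- exp(log_num - Md)
  b <- exp(log_den - Md)
  abar <- mean(a)
  bbar <- mean(b)
  if (bbar == 0)
    stop("degenerate training likelihood: denominator underflowed to zero")
  prob <- abar / bbar
  R <- length(a)
  mc_se <- if (R > 1L && abar > 0) {
    rel <- var(a) / abar^2 + var(b) / bbar^2 - 2 * cov(a, b) / (abar * bbar)
    prob * sqrt(max(rel, 0) / R)
  } else 0
  list(prob = min(max(prob, 0), 1), mc_se = mc_se)
}

#' Prediction probability ratio for one new location
#'
#' Estimates `p(Y(s_new) = 1 | Y) = Phi_{n+1}(m*, Sigma*_tilde) /
#' Phi_n(m, Sigma_tilde)`. The `n` training e-terms are computed once per
#' draw and reused verbatim in the numerator (the extended factor agrees
#' with the training factor on its top `n x n` block); only the one
#' additional term
#' `e_{n+1} = Phi((m_{n+1} - sum_j v_j qnorm(u_j e_j)) / sqrt(f_new))`
#' is added, where `v` is the bottom row of the extended factor. No fresh
#' uniform enters this term: position `n + 1` has no successors to
#' condition on it, so the `(n+1)`-th uniform of the nominal draw vector
#' never appears in either product.
#'
#' @param factor an [nngp_factor()].
#' @param extended an [extend_factor()] result built with `new_sign = +1`.
#' @param draws a [sov_draws()] for dimension `n`.
#' @param denominator optional [estimate_log_cdf()] result for the training
#'   block (must have been computed with `keep_z = TRUE` and these same
#'   draws); computed on the fly when missing.
#' @param clamp_eps clamp for the probit transform.
#' @return An object of class `probit_prediction` with `prob` (clipped to
#'   `[0, 1]`), `mc_se`, the numerator/denominator log-CDF values, and the
#'   denominator estimate used.
#' @export
predict_probability <- function(factor, extended, draws, denominator = NULL,
                                clamp_eps = 1e-10) {
  stopifnot(inherits(factor, "nngp_factor"),
            inherits(extended, "extended_factor"))
  if (is.null(denominator) || is.null(denominator$z)) {
    denominator <- tryCatch(
      estimate_log_cdf(factor$m_vec, factor$L, draws, clamp_eps,
                       keep_z = TRUE),
      error = function(e) stop("training likelihood failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  s <- drop(denominator$z %*% extended$bottom_row)
  log_e_new <- pnorm((extended$m_new - s) / sqrt(extended$f_new),
                     log.p = TRUE)
  log_num <- denominator$per_sample_log_products + log_e_new
  r <- .ratio_estimate(log_num, denominator$per_sample_log_products)
  Mn <- max(log_num)
  log_num_value <- if (is.finite(Mn)) Mn + log(mean(exp(log_num - Mn))) else -Inf
  structure(list(prob = r$prob, mc_se = r$mc_se,
                 log_numerator = log_num_value,
                 log_denominator = denominator$log_value,
                 denominator = denominator, R = denominator$R),
            class = "probit_prediction")
}

#' @export
print.probit_prediction <- function(x, ...) {
  cat(sprintf("probit_prediction: %.4f (mc se %.2g, R = %d)\n",
              x$prob, x$mc_se, x$R))
  invisible(x)
}
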