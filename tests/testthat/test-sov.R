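test_that("sov terms follow the recursion (hand-traced cases)", {
  # n = 1: e1 = Phi(m1 / l11), independent of u
  expect_equal(sov_terms(0, matrix(sqrt(2)), 0.37), 0.5)
  # diagonal factor: no cross terms, e_i = Phi(m_i / l_ii) for any u
  m <- c(0.3, -0.2, 1.1)
  L <- diag(c(1, 2, 0.5))
  for (u in list(c(0.1, 0.5, 0.9), c(0.99, 0.01, 0.42)))
    expect_equal(sov_terms(m, L, u), pnorm(m / diag(L)))
  # n = 2 manual trace of the recursion
  L2 <- rbind(c(1, 0), c(0.5, sqrt(0.75)))
  e <- sov_terms(c(0, 0), L2, c(0.8, 0.5))
  expect_equal(e[1], 0.5)
  expect_equal(e[2], pnorm(-0.5 * qnorm(0.8 * 0.5) / sqrt(0.75)),
               tolerance = 1e-12)
  expect_error(sov_terms(c(0, 0), rbind(c(1, 0), c(0, -1)), c(0.5, 0.5)),
               "diagonal")
})

test_that("vectorized estimator agrees with the scalar recursion per draw", {
  d <- random_dataset(12, seed = 21)
  pars <- random_params(seed = 22)
  f <- nngp_factor(d, pars, m = 5)
  dr <- sov_draws(12, R = 6, seed = 23)
  est <- estimate_log_cdf(f$m_vec, f$L, dr)
  manual <- vapply(seq_len(6), function(r)
    sum(log(sov_terms(f$m_vec, f$L, dr$u[r, ]))), 0)
  expect_equal(est$per_sample_log_products, manual, tolerance = 1e-12)
})

test_that("log-CDF estimate has zero variance when Sigma is diagonal", {
  m <- c(0.4, -1.2, 0.9, 0)
  est <- estimate_log_cdf(m, diag(4), sov_draws(4, 100, seed = 5))
  expect_equal(est$log_value, sum(pnorm(m, log.p = TRUE)), tolerance = 1e-12)
  expect_equal(est$mc_se_log, 0)
  # n = 1, m = 0: exactly log(1/2)
  est1 <- estimate_log_cdf(0, diag(1), sov_draws(1, 10, seed = 5))
  expect_equal(est1$log_value, log(0.5))
})

test_that("an all-underflow likelihood raises a degenerate error", {
  expect_error(
    estimate_log_cdf(rep(-1e160, 3), diag(3), sov_draws(3, 20, seed = 1)),
    "degenerate")
})

test_that("estimator matches the quadrature oracle at small n", {
  # bivariate orthant with rho = 0.5: exact value 1/3
  L <- t(chol(rbind(c(1, 0.5), c(0.5, 1))))
  est <- estimate_log_cdf(c(0, 0), L, sov_draws(2, 50000, seed = 8))
  expect_lt(abs(exp(est$log_value) - 1 / 3),
            4 * est$mc_se_log * exp(est$log_value) + 1e-4)
  # random covariance, n = 3
  for (s in 1:3) {
    d <- random_dataset(3, seed = 30 + s)
    pars <- random_params(seed = 40 + s)
    S <- reference_dense_sigma(d, pars)
    m <- rnorm(3)
    est <- estimate_log_cdf(m, t(chol(S)), sov_draws(3, 50000, seed = s))
    truth <- reference_quadrature_cdf(m, S)
    expect_lt(abs(exp(est$log_value) - truth),
              4 * est$mc_se_log * exp(est$log_value) + 1e-5)
  }
})

test_that("prediction reverts to the independence limit for weak correlation", {
  d <- random_dataset(10, seed = 55)
  pars <- probit_params(sigma2 = 0.7, phi = 5000)  # correlations ~ 0
  f <- nngp_factor(d, pars, m = 5)
  dr <- sov_draws(10, 4000, seed = 56)
  ext <- extend_factor(f, c(0.5, 0.5))
  p <- predict_probability(f, ext, dr)
  expect_equal(p$prob, pnorm(0 / sqrt(1.7)), tolerance = 0.02)
})

test_that("complementing all labels complements the prediction (beta = 0)", {
  set.seed(60)
  co <- matrix(runif(60), 30, 2)
  y <- rbinom(30, 1, 0.5)
  pars <- probit_params(sigma2 = 1, phi = 10)
  dr <- sov_draws(30, 20000, seed = 61)
  test_pt <- c(0.41, 0.52)
  f1 <- nngp_factor(spatial_dataset(co, y), pars, m = 10)
  f2 <- nngp_factor(spatial_dataset(co, 1 - y), pars, m = 10)
  p1 <- predict_probability(f1, extend_factor(f1, test_pt), dr)
  p2 <- predict_probability(f2, extend_factor(f2, test_pt), dr)
  tol <- 4 * sqrt(p1$mc_se^2 + p2$mc_se^2) + 0.01
  expect_lt(abs(p1$prob - (1 - p2$prob)), tol)
})

test_that("denominator e-terms are reused bitwise in the numerator", {
  d <- random_dataset(20, seed = 70)
  pars <- random_params(seed = 71)
  f <- nngp_factor(d, pars, m = 8)
  dr <- sov_draws(20, 500, seed = 72)
  standalone <- estimate_log_cdf(f$m_vec, f$L, dr, keep_z = TRUE)
  p <- predict_probability(f, extend_factor(f, c(0.2, 0.9)), dr)
  expect_identical(p$denominator$per_sample_log_products,
                   standalone$per_sample_log_products)
  expect_identical(p$denominator$z, standalone$z)
  # and passing the precomputed denominator changes nothing
  p2 <- predict_probability(f, extend_factor(f, c(0.2, 0.9)), dr,
                            denominator = standalone)
  expect_identical(p$prob, p2$prob)
})

test_that("probabilities and log-CDF values respect their ranges", {
  for (s in 1:8) {
    d <- random_dataset(15, seed = 80 + s)
    pars <- random_params(seed = 90 + s)
    f <- nngp_factor(d, pars, m = 6)
    dr <- sov_draws(15, 300, seed = s)
    est <- estimate_log_cdf(f$m_vec, f$L, dr)
    expect_lte(est$log_value, 0)
    expect_true(is.finite(est$mc_se_log))
    set.seed(s)
    p <- predict_probability(f, extend_factor(f, runif(2)), dr)
    expect_gte(p$prob, 0)
    expect_lte(p$prob, 1)
  }
})
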