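test_that("mse is the mean of squared differences", {
  expect_equal(mse(c(0.2, 0.7), c(0.2, 0.7)), 0)
  expect_equal(mse(c(0, 1), c(1, 0)), 1)
  expect_equal(mse(c(0.2, 0.4), c(0.1, 0.6)), 0.025)
  expect_error(mse(1:3 / 10, 1:2 / 10), "length mismatch")
})

test_that("a single-point grid is returned as the fit", {
  d <- random_dataset(12, seed = 15)
  fit <- grid_search_fit(d, param_grid(0.9, 12), R = 200, seed = 1)
  expect_equal(fit$best_params$sigma2, 0.9)
  expect_equal(fit$best_params$phi, 12)
  expect_equal(dim(fit$log_likelihood_surface), c(1L, 1L))
})

test_that("argmax ties break toward the smallest (sigma2, phi)", {
  surf <- matrix(c(-5, -3, -3, -4), 2, 2)  # ties at (1,2) and (2,1)
  idx <- probitNNGP:::.argmax_lex(surf)
  expect_equal(unname(idx), c(1L, 2L))
})

test_that("surface values match the dense-factor likelihood at saturation", {
  d <- random_dataset(12, seed = 16)
  grid <- param_grid(c(0.8, 1.3), c(6, 20))
  dr <- sov_draws(12, 2000, seed = 17)
  fit <- grid_search_fit(d, grid, m = 11, draws = dr)
  for (i in 1:2) for (j in 1:2) {
    pars <- probit_params(sigma2 = grid$sigma2_values[i],
                          phi = grid$phi_values[j])
    S <- reference_dense_sigma(d, pars)
    ord <- order_by_coordinate_sum(d$coords)
    ref <- estimate_log_cdf(numeric(12), t(chol(S[ord, ord])), dr)
    expect_equal(fit$log_likelihood_surface[i, j], ref$log_value,
                 tolerance = 1e-7)
  }
})

test_that("the fitted surface is invariant to training-row permutation", {
  d <- random_dataset(30, seed = 18)
  grid <- param_grid(c(0.7, 1.2), c(8, 25))
  fit1 <- grid_search_fit(d, grid, m = 6, R = 500, seed = 19)
  set.seed(20)
  perm <- sample(30)
  fit2 <- grid_search_fit(spatial_dataset(d$coords[perm, ], d$y[perm]),
                          grid, m = 6, R = 500, seed = 19)
  expect_identical(fit1$log_likelihood_surface, fit2$log_likelihood_surface)
})

test_that("on average the likelihood prefers the truth to a no-correlation model", {
  # well-identified configuration (nearest-neighbor latent correlation ~ 0.6)
  diffs <- vapply(1:10, function(r) {
    repl <- simulate_replicate(sim_config(12, 1, 6, 0, "random",
                                          seed = 2100 + r))
    fit <- grid_search_fit(repl$train, param_grid(1, c(6, 300)), m = 15,
                           R = 2000, seed = 60 + r)
    s <- fit$log_likelihood_surface
    s[1, 1] - s[1, 2]
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("batch prediction handles empty input, bad rows, and stays in [0, 1]", {
  d <- random_dataset(25, seed = 26)
  pars <- probit_params(sigma2 = 1, phi = 10)
  empty <- predict_at_locations(d, pars, matrix(numeric(0), 0, 2))
  expect_equal(nrow(empty), 0L)
  expect_s3_class(empty, "prediction_result")

  set.seed(27)
  tc <- rbind(matrix(runif(8), 4, 2), d$coords[7, ])  # last one coincident
  res <- predict_at_locations(d, pars, tc, m = 8, R = 500, seed = 28)
  expect_equal(res$index, 1:5)
  expect_true(all(res$status[1:4] == "ok"))
  expect_match(res$status[5], "coincides")
  expect_true(is.na(res$prob[5]))
  expect_true(all(res$prob[1:4] >= 0 & res$prob[1:4] <= 1))
  expect_true(all(res$mc_se[1:4] >= 0))
})

test_that("batch prediction matches the dense-factor reference at small n", {
  d <- random_dataset(40, seed = 29)
  pars <- probit_params(sigma2 = 1, phi = 10)
  set.seed(30)
  tc <- matrix(runif(10), 5, 2)
  a <- predict_at_locations(d, pars, tc, m = 15, R = 5000, seed = 31)
  b <- reference_full_predict(d, pars, tc, R = 5000, seed = 32)
  tol <- 3 * sqrt(a$mc_se^2 + b$mc_se^2) + 0.01  # small NNGP bias allowance
  expect_true(all(abs(a$prob - b$prob) < tol))
})

test_that("multi-location prediction reuses one factor and one draw set", {
  d <- random_dataset(30, seed = 33)
  pars <- probit_params(sigma2 = 1, phi = 10)
  set.seed(34)
  tc <- matrix(runif(6), 3, 2)
  batch <- predict_at_locations(d, pars, tc, m = 8, R = 2000, seed = 35)
  # element-wise pipeline with the same draws gives identical numbers
  f <- nngp_factor(d, pars, m = 8)
  dr <- sov_draws(30, 2000, seed = 35)
  den <- estimate_log_cdf(f$m_vec, f$L, dr, keep_z = TRUE)
  single <- vapply(1:3, function(k)
    predict_probability(f, extend_factor(f, tc[k, ]), dr,
                        denominator = den)$prob, 0)
  expect_equal(batch$prob, single, tolerance = 1e-12)
})
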