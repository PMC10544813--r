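test_that("coordinate-sum ordering is stable and deterministic", {
  expect_equal(order_by_coordinate_sum(rbind(c(0, 0), c(1, 0), c(0.2, 0.3))),
               c(1L, 3L, 2L))
  # equal sums preserve original order
  expect_equal(order_by_coordinate_sum(rbind(c(0, 1), c(1, 0), c(0.5, 0.5))),
               1:3)
  expect_equal(order_by_coordinate_sum(rbind(c(0.4, 0.7))), 1L)
})

test_that("neighbor sets are the nearest predecessors (vs exhaustive oracle)", {
  # first set empty; early sets take all predecessors
  co <- matrix(runif(20), 10, 2)
  nb <- build_neighbor_sets(co, m = 4)
  expect_identical(nb[[1]], integer(0))
  for (i in 2:5) expect_identical(nb[[i]], seq_len(i - 1L))
  # collinear points
  line <- cbind(seq(0, 1, length.out = 5), 0)
  expect_identical(build_neighbor_sets(line, m = 2),
                   brute_force_neighbors(line, 2))
  # random configurations
  for (s in 1:10) {
    set.seed(300 + s)
    co <- matrix(runif(80), 40, 2)
    expect_identical(build_neighbor_sets(co, m = 6),
                     brute_force_neighbors(co, 6))
  }
  expect_error(build_neighbor_sets(co, m = 0), "positive")
})

test_that("saturated coefficients reproduce the dense precision exactly", {
  for (s in 1:5) {
    n <- c(5L, 12L, 20L)[1L + (s %% 3L)]
    d <- random_dataset(n, seed = 400 + s)
    pars <- random_params(seed = 500 + s)
    pr <- marginal_problem(d, pars)
    nb <- build_neighbor_sets(d$coords, m = n - 1L)
    cf <- nngp_coefficients(pr, nb)
    S <- sigma_block(pr, seq_len(n), seq_len(n))
    IA <- diag(n) - as.matrix(cf$A)
    Q <- t(IA) %*% diag(1 / cf$F, n) %*% IA
    expect_equal(Q, solve(S), tolerance = 1e-8)
    # conditional variances cannot exceed the marginal variance
    expect_true(all(cf$F <= 1 + pars$sigma2 + 1e-12))
    expect_true(all(cf$F > 0))
  }
  # n = 1: empty A, unconditioned variance
  d1 <- random_dataset(1, seed = 1)
  pars <- probit_params(sigma2 = 0.8, phi = 5)
  cf1 <- nngp_coefficients(marginal_problem(d1, pars),
                           build_neighbor_sets(d1$coords, 3))
  expect_equal(cf1$F, 1.8)
  expect_equal(length(cf1$a_val), 0L)
})

test_that("cholesky columns solve (I - A) l_j = sqrt(f_j) e_j", {
  # n = 1
  d1 <- random_dataset(1, seed = 2)
  pars <- probit_params(sigma2 = 1, phi = 5)
  f1 <- nngp_factor(d1, pars, m = 1)
  expect_equal(f1$L, matrix(sqrt(2)))

  # saturation: L equals the dense Cholesky factor of Sigma
  for (s in 1:5) {
    n <- 10L + s
    d <- random_dataset(n, seed = 600 + s)
    pars <- random_params(seed = 700 + s)
    f <- nngp_factor(d, pars, m = n - 1L)
    S <- reference_dense_sigma(d, pars)
    expect_equal(f$L, t(chol(S[f$order, f$order])), tolerance = 1e-8)
  }

  # genuinely sparse case: L L' reconstructs the NNGP covariance
  d <- random_dataset(25, seed = 42)
  pars <- random_params(seed = 43)
  f <- nngp_factor(d, pars, m = 4)
  expect_equal(tcrossprod(f$L), dense_sigma_tilde(f$A, f$F),
               tolerance = 1e-8)
  # accepts a plain (A, F) pair too
  expect_equal(cholesky_columns(f$A, f$F), f$L)
})

test_that("column solves are bit-identical for any worker count", {
  d <- random_dataset(60, seed = 9)
  pars <- random_params(seed = 10)
  pr <- marginal_problem(spatial_dataset(
    d$coords[order_by_coordinate_sum(d$coords), , drop = FALSE],
    d$y[order_by_coordinate_sum(d$coords)]), pars)
  nb <- build_neighbor_sets(pr$coords, 8)
  cf <- nngp_coefficients(pr, nb)
  L1 <- cholesky_columns(cf, workers = 1L)
  L3 <- cholesky_columns(cf, workers = 3L)
  expect_identical(L1, L3)
})

test_that("factor extension matches the dense Cholesky at saturation", {
  for (s in 1:5) {
    n <- 8L + s
    d <- random_dataset(n, seed = 800 + s)
    pars <- random_params(seed = 900 + s)
    f <- nngp_factor(d, pars, m = n)  # extension conditions on all n points
    set.seed(1000 + s)
    new_coord <- runif(2)
    ext <- extend_factor(f, new_coord, new_sign = 1)
    # dense Sigma* in ordered space, new location last
    pr <- marginal_problem(spatial_dataset(f$coords, f$y), pars)
    S <- sigma_block(pr, seq_len(n), seq_len(n))
    cross <- drop(exponential_covariance(f$coords, rbind(new_coord),
                                         pars$sigma2, pars$phi)) * f$sign
    Sstar <- rbind(cbind(S, cross), c(cross, 1 + pars$sigma2))
    Lstar <- t(chol(Sstar))
    expect_equal(ext$bottom_row, unname(Lstar[n + 1, seq_len(n)]),
                 tolerance = 1e-8)
    expect_equal(sqrt(ext$f_new), unname(Lstar[n + 1, n + 1]),
                 tolerance = 1e-8)
  }
})

test_that("a far-away location reverts to the unconditional law", {
  d <- random_dataset(30, seed = 77)
  pars <- probit_params(sigma2 = 1.4, phi = 30)
  f <- nngp_factor(d, pars, m = 10)
  ext <- extend_factor(f, c(250, 250))  # correlations ~ exp(-30 * 350)
  expect_lt(max(abs(ext$a)), 1e-12)
  expect_equal(ext$f_new, 2.4, tolerance = 1e-12)
  expect_lt(max(abs(ext$bottom_row)), 1e-12)
  expect_error(extend_factor(f, d$coords[3, ]), "coincides")
})

test_that("KL divergence to the full covariance is non-increasing in m", {
  d <- random_dataset(15, seed = 1234)
  pars <- probit_params(sigma2 = 1, phi = 8)
  S <- reference_dense_sigma(d, pars)
  ord <- order_by_coordinate_sum(d$coords)
  S_o <- S[ord, ord]
  kl <- vapply(1:14, function(m) {
    f <- nngp_factor(d, pars, m = m)
    as.numeric(kl_gauss(S_o, dense_sigma_tilde(f$A, f$F)))
  }, 0)
  expect_true(all(diff(kl) <= 1e-9))
  expect_lt(kl[14], 1e-10)  # exact at saturation
})

test_that("factor quantities round-trip the ordering permutation exactly", {
  d <- random_dataset(40, seed = 31)
  pars <- random_params(seed = 32)
  f <- nngp_factor(d, pars, m = 6)
  expect_identical(f$coords, d$coords[f$order, , drop = FALSE])
  expect_identical(f$y, d$y[f$order])
  # inverse permutation restores original row order
  inv <- order(f$order)
  expect_identical(f$coords[inv, , drop = FALSE], d$coords)
  # a row-permuted dataset yields the identical factor
  set.seed(33)
  perm <- sample(40)
  f2 <- nngp_factor(spatial_dataset(d$coords[perm, ], d$y[perm]), pars, m = 6)
  expect_identical(f2$L, f$L)
  expect_identical(f2$F, f$F)
})
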