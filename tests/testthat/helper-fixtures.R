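# fixtures are generated in code; no data files

random_dataset <- function(n, seed = NULL, p = 0L) {
  if (!is.null(seed)) set.seed(seed)
  coords <- matrix(runif(2L * n), n, 2L)
  y <- rbinom(n, 1L, 0.5)
  X <- if (p > 0L) matrix(rnorm(n * p), n, p) else NULL
  spatial_dataset(coords, y, X)
}

random_params <- function(seed = NULL, p = 0L) {
  if (!is.null(seed)) set.seed(seed)
  probit_params(beta = if (p > 0L) rnorm(p) else numeric(0),
                sigma2 = runif(1, 0.5, 2), phi = runif(1, 2, 30))
}

# independent neighbor oracle: full distance matrix + exhaustive sort
brute_force_neighbors <- function(coords, m) {
  D <- as.matrix(dist(coords))
  n <- nrow(coords)
  out <- vector("list", n)
  out[[1L]] <- integer(0)
  for (i in seq_len(n)[-1L]) {
    pred <- seq_len(i - 1L)
    k <- min(m, i - 1L)
    out[[i]] <- sort.int(pred[order(D[i, pred])][seq_len(k)])
  }
  out
}

# dense NNGP covariance implied by (A, F), for small-n checks
dense_sigma_tilde <- function(A, F) {
  n <- length(F)
  IA <- diag(n) - as.matrix(A)
  solve(t(IA) %*% diag(1 / F, n) %*% IA)
}

kl_gauss <- function(S_true, S_approx) {
  n <- nrow(S_true)
  0.5 * (sum(diag(solve(S_approx, S_true))) - n +
         determinant(S_approx)$modulus - determinant(S_true)$modulus)
}
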