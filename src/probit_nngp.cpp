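#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Separation-of-variables recursion evaluated for all Monte-Carlo draws at
// once. m holds the CDF upper limits, Lt is the *transpose* of the
// lower-triangular factor (so row i of L is the contiguous column i of Lt),
// U is the R x n matrix of uniforms. The per-draw products of the e-terms
// are accumulated in log space; Z stores the probit-transformed
// conditioning variables z_{r,i} = qnorm(clamp(u_{r,i} e_{r,i})) that later
// dimensions (and the prediction numerator) condition on.
// [[Rcpp::export]]
List cpp_sov(const arma::vec& m, const arma::mat& Lt, const arma::mat& U,
             const bool keep_z, const double clamp_eps) {
  const arma::uword n = m.n_elem;
  const arma::uword R = U.n_rows;
  if (Lt.n_rows != n || Lt.n_cols != n)
    stop("factor dimension does not match the mean vector");
  if (U.n_cols != n)
    stop("draw matrix must have one column per dimension");
  arma::vec logprod(R, arma::fill::zeros);
  arma::mat Z(R, n);
  arma::vec s(R, arma::fill::zeros);
  const double hi = 1.0 - clamp_eps;
  for (arma::uword i = 0; i < n; ++i) {
    const double lii = Lt(i, i);
    if (!(lii > 0.0))
      stop("triangular factor has a non-positive diagonal entry");
    if (i == 0) {
      s.zeros();
    } else {
      s = Z.cols(0, i - 1) * Lt(arma::span(0, i - 1), i);
    }
    for (arma::uword r = 0; r < R; ++r) {
      const double x = (m(i) - s(r)) / lii;
      const double loge = R::pnorm(x, 0.0, 1.0, 1, 1);
      logprod(r) += loge;
      double ue = U(r, i) * std::exp(loge);
      if (ue < clamp_eps) ue = clamp_eps;
      else if (ue > hi) ue = hi;
      Z(r, i) = R::qnorm(ue, 0.0, 1.0, 1, 0);
    }
  }
  if (keep_z)
    return List::create(Named("logprod") = logprod, Named("z") = Z);
  return List::create(Named("logprod") = logprod);
}

// Forward substitution (I - A) l_j = sqrt(f_j) eta_j for columns j0..j1
// (0-based) of the NNGP Cholesky factor. nn_ptr / nn_idx give the row-wise
// sparsity of the strictly-lower-triangular A (0-based, <= m entries per
// row), a_val the matching coefficients. Each column costs O(n m).
// [[Rcpp::export]]
arma::mat cpp_chol_columns(const IntegerVector& nn_ptr,
                           const IntegerVector& nn_idx,
                           const arma::vec& a_val, const arma::vec& f,
                           const int j0, const int j1) {
  const int n = f.n_elem;
  if (j0 < 0 || j1 >= n || j1 < j0) stop("invalid column range");
  arma::mat L(n, j1 - j0 + 1, arma::fill::zeros);
  for (int j = j0; j <= j1; ++j) {
    double* col = L.colptr(j - j0);
    if (!(f(j) > 0.0)) stop("conditional variances must be positive");
    col[j] = std::sqrt(f(j));
    for (int i = j + 1; i < n; ++i) {
      double acc = 0.0;
      for (int k = nn_ptr[i]; k < nn_ptr[i + 1]; ++k)
        acc += a_val(k) * col[nn_idx[k]];
      col[i] = acc;
    }
  }
  return L;
}

// Sequential conditional (Vecchia) regression coefficients and variances
// for Sigma = I + D C D with an exponential kernel on already-ordered
// coordinates: row i of A is Sigma[i, N(i)] Sigma[N(i), N(i)]^{-1} and
// f_i = Sigma_ii - A[i, N(i)] Sigma[N(i), i]. Each row costs O(m^3).
// [[Rcpp::export]]
List cpp_nngp_coefficients(const arma::mat& coords, const arma::vec& sgn,
                           const IntegerVector& nn_ptr,
                           const IntegerVector& nn_idx,
                           const double sigma2, const double phi) {
  const int n = coords.n_rows;
  const int nnz = nn_idx.size();
  arma::vec a_val(nnz, arma::fill::zeros);
  arma::vec f(n);
  const double diag = 1.0 + sigma2;
  for (int i = 0; i < n; ++i) {
    const int p0 = nn_ptr[i];
    const int mi = nn_ptr[i + 1] - p0;
    if (mi == 0) {  // first ordered location: unconditioned variance
      f(i) = diag;
      continue;
    }
    arma::mat S(mi, mi);
    arma::vec sv(mi);
    for (int q = 0; q < mi; ++q) {
      const int iq = nn_idx[p0 + q];
      const double dxq = coords(iq, 0) - coords(i, 0);
      const double dyq = coords(iq, 1) - coords(i, 1);
      sv(q) = sgn(iq) * sgn(i) * sigma2 *
              std::exp(-phi * std::sqrt(dxq * dxq + dyq * dyq));
      S(q, q) = diag;
      for (int k = q + 1; k < mi; ++k) {
        const int ik = nn_idx[p0 + k];
        const double dx = coords(iq, 0) - coords(ik, 0);
        const double dy = coords(iq, 1) - coords(ik, 1);
        const double v = sgn(iq) * sgn(ik) * sigma2 *
                         std::exp(-phi * std::sqrt(dx * dx + dy * dy));
        S(q, k) = v;
        S(k, q) = v;
      }
    }
    arma::vec a;
    const bool ok = arma::solve(a, S, sv,
                                arma::solve_opts::likely_sympd +
                                arma::solve_opts::no_approx);
    if (!ok)
      stop("singular neighbor sub-block at ordered index %d "
           "(coincident locations?)", i + 1);
    for (int q = 0; q < mi; ++q) a_val(p0 + q) = a(q);
    f(i) = diag - arma::dot(a, sv);
    if (!(f(i) > 0.0))
      stop("non-positive conditional variance at ordered index %d", i + 1);
  }
  return List::create(Named("a_val") = a_val, Named("f") = f);
}
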