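// Non-negative matrix factorization by HALS block coordinate descent, and
// non-negative least-squares usage refits. Hot loops of the consensus
// factorization; everything else stays in R.
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

static const double EPS = 1e-12;

// Frobenius error ||M - W H||_F using the expansion
// ||M||^2 - 2 tr(W' M H') + tr((W'W)(H H')); avoids forming W H.
static double frob_err(double m2, const mat& W, const mat& H, const mat& MHt) {
  double cross = accu(W % MHt);
  double quad  = accu((W.t() * W) % (H * H.t()));
  double v = m2 - 2.0 * cross + quad;
  return std::sqrt(std::max(v, 0.0));
}

// One HALS sweep over the columns of W (given fixed H, with C = M H' and
// G = H H' precomputed), then over the rows of H.
// [[Rcpp::export(name = ".cpp_nmf_hals")]]
Rcpp::List cpp_nmf_hals(const arma::mat& M, int k, unsigned int seed,
                        int max_iter, double tol) {
  const uword n = M.n_rows, g = M.n_cols;
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // Only W is seeded randomly; H starts at 0 and receives the first
  // coordinate-descent update, so the whole trajectory is equivariant under
  // permutation of the gene axis of M.
  double mbar = accu(M) / (double)(n * g);
  double scale = std::sqrt(std::max(mbar, EPS) / (double)k);
  mat W(n, (uword)k), H((uword)k, g, fill::zeros);
  for (uword j = 0; j < (uword)k; ++j)
    for (uword i = 0; i < n; ++i) W(i, j) = scale * (0.05 + unif(rng));

  const double m2 = accu(M % M);
  double err_prev = datum::inf, err = datum::inf;
  bool converged = false;
  int it = 0;
  const int check_every = 5;

  for (it = 1; it <= max_iter; ++it) {
    // --- update H rows (Gauss-Seidel) ---
    mat WtM = W.t() * M;          // k x g
    mat F   = W.t() * W;          // k x k
    for (uword j = 0; j < (uword)k; ++j) {
      double fjj = F(j, j);
      if (fjj <= EPS) continue;
      rowvec hj = H.row(j) + (WtM.row(j) - F.row(j) * H) / fjj;
      H.row(j) = clamp(hj, 0.0, datum::inf);
    }
    // --- update W columns ---
    mat MHt = M * H.t();          // n x k
    mat G   = H * H.t();          // k x k
    for (uword j = 0; j < (uword)k; ++j) {
      double gjj = G(j, j);
      if (gjj <= EPS) continue;
      vec wj = W.col(j) + (MHt.col(j) - W * G.col(j)) / gjj;
      W.col(j) = clamp(wj, 0.0, datum::inf);
    }
    // guard against a dead component: reseed it randomly
    for (uword j = 0; j < (uword)k; ++j) {
      if (accu(W.col(j)) <= EPS) {
        for (uword i = 0; i < n; ++i) W(i, j) = scale * (0.05 + unif(rng));
      }
    }
    if (it % check_every == 0 || it == max_iter) {
      err = frob_err(m2, W, H, MHt);  // MHt = M H' is current: H unchanged
                                      // since the W update
      bool exact = err <= 1e-10 * std::sqrt(std::max(m2, EPS));
      if (exact || (std::isfinite(err_prev) &&
          (err_prev - err) <= tol * std::max(err_prev, EPS))) {
        converged = true;
        break;
      }
      err_prev = err;
    }
  }
  {
    mat MHt = M * H.t();
    err = frob_err(m2, W, H, MHt);
  }

  // absorb row scales of H into W so H rows lie on the simplex
  vec rs = sum(H, 1);
  for (uword i = 0; i < (uword)k; ++i) {
    double s = rs(i);
    if (s > EPS) { H.row(i) /= s; W.col(i) *= s; }
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("frobenius_error") = err,
                            Rcpp::Named("n_iter") = it,
                            Rcpp::Named("converged") = converged);
}

// Rowwise NNLS: for each row m of M solve min_u ||u H - m||_2, u >= 0,
// by cyclic coordinate descent on the normal equations.
// [[Rcpp::export(name = ".cpp_nnls_rows")]]
arma::mat cpp_nnls_rows(const arma::mat& H, const arma::mat& M,
                        int max_iter = 400, double tol = 1e-10) {
  const uword k = H.n_rows, n = M.n_rows;
  mat G = H * H.t();                      // k x k Gram
  mat C = M * H.t();                      // n x k
  mat U(n, k, fill::zeros);
  vec diagG = G.diag();

  for (uword i = 0; i < n; ++i) {
    rowvec u(k, fill::zeros);
    rowvec ci = C.row(i);
    for (int it = 0; it < max_iter; ++it) {
      double delta = 0.0;
      for (uword j = 0; j < k; ++j) {
        if (diagG(j) <= EPS) continue;
        double grad = ci(j) - dot(u, G.col(j));
        double unew = std::max(0.0, u(j) + grad / diagG(j));
        delta = std::max(delta, std::abs(unew - u(j)));
        u(j) = unew;
      }
      if (delta < tol * (1.0 + u.max())) break;
    }
    U.row(i) = u;
  }
  return U;
}
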