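// Lawson-Hanson active-set non-negative least squares.
//
// The deconvolution solves one small NNLS problem per subject per
// regularization weight; power and calibration studies run tens of
// thousands of them, hence the compiled solver.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::NumericVector nnls_cpp(const arma::mat& A, const arma::vec& b,
                             int max_iter = 0) {
  const uword n = A.n_cols;
  if (A.n_rows != b.n_elem) Rcpp::stop("nrow(A) must equal length(b)");
  if (max_iter <= 0) max_iter = 5 * static_cast<int>(n) + 50;

  std::vector<bool> passive(n, false);
  vec x(n, fill::zeros);
  vec w = A.t() * (b - A * x);
  const double tol = 10.0 * datum::eps * norm(A, 1) *
                     static_cast<double>(std::max(A.n_rows, A.n_cols));

  auto solve_passive = [&](vec& z) {
    std::vector<uword> idx;
    for (uword j = 0; j < n; ++j)
      if (passive[j]) idx.push_back(j);
    uvec P(idx);
    vec zp;
    bool ok = solve(zp, A.cols(P), b, solve_opts::fast);
    if (!ok) zp = pinv(A.cols(P)) * b;
    z.zeros(n);
    z(P) = zp;
    return P;
  };

  int iter = 0;
  while (true) {
    // find most violated dual among the active (zero-clamped) variables
    double wmax = -datum::inf;
    sword jmax = -1;
    for (uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
    if (jmax < 0 || wmax <= tol) break;
    passive[jmax] = true;

    vec z;
    solve_passive(z);
    while (true) {
      if (++iter > max_iter)
        Rcpp::stop("nnls did not converge in %d iterations", max_iter);
      bool feasible = true;
      double alpha = 1.0;
      for (uword j = 0; j < n; ++j)
        if (passive[j] && z(j) <= 0.0) {
          feasible = false;
          double a = x(j) / (x(j) - z(j));
          if (a < alpha) alpha = a;
        }
      if (feasible) { x = z; break; }
      x += alpha * (z - x);
      for (uword j = 0; j < n; ++j)
        if (passive[j] && x(j) <= tol) { passive[j] = false; x(j) = 0.0; }
      solve_passive(z);
    }
    w = A.t() * (b - A * x);
  }
  return Rcpp::wrap(x);
}
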