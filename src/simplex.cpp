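#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Bounded-variable primal simplex pivot loop (Bland's entering rule),
// the compiled twin of the reference implementation in R/lp.R. The
// algorithm, tolerances and tie-breaking are identical; only the
// language differs, so R and C++ paths take the same pivot sequence.
// basis is 1-based (R convention). Returns status 0 = optimal,
// 1 = unbounded, 2 = iteration limit.
// [[Rcpp::export(name = ".simplex_iterate_cpp")]]
List simplex_iterate_cpp(const arma::vec& cvec, const arma::mat& A,
                         const arma::vec& b, const arma::vec& u,
                         IntegerVector basis_in,
                         LogicalVector at_upper_in, double tol,
                         int max_iter) {
  const int m = A.n_rows, n = A.n_cols;
  arma::uvec basis(m);
  for (int i = 0; i < m; ++i) basis[i] = basis_in[i] - 1;
  std::vector<bool> at_upper(n);
  for (int j = 0; j < n; ++j) at_upper[j] = at_upper_in[j];

  arma::vec x(n, arma::fill::zeros);
  for (int j = 0; j < n; ++j)
    if (at_upper[j] && std::isfinite(u[j])) x[j] = u[j];
  std::vector<bool> in_basis(n, false);
  for (int i = 0; i < m; ++i) in_basis[basis[i]] = true;

  arma::mat B = A.cols(basis);
  {
    // x_basis = B^{-1} (b - N x_N)
    arma::vec rhs(m, arma::fill::zeros);
    for (int j = 0; j < n; ++j)
      if (!in_basis[j] && x[j] != 0.0) rhs += A.col(j) * x[j];
    arma::vec xb = arma::solve(B, b - rhs);
    for (int i = 0; i < m; ++i) x[basis[i]] = xb[i];
  }

  int status = 2;
  for (int iter = 0; iter < max_iter; ++iter) {
    B = A.cols(basis);
    arma::vec cb(m);
    for (int i = 0; i < m; ++i) cb[i] = cvec[basis[i]];
    arma::vec y = arma::solve(B.t(), cb);
    // entering: Bland, smallest eligible index
    int j_enter = -1;
    for (int j = 0; j < n; ++j) {
      if (in_basis[j]) continue;
      const double d = cvec[j] - arma::dot(y, A.col(j));
      if ((!at_upper[j] && d > tol) || (at_upper[j] && d < -tol)) {
        j_enter = j;
        break;
      }
    }
    if (j_enter < 0) { status = 0; break; }
    const bool up = !at_upper[j_enter];
    const double sgn = up ? 1.0 : -1.0;
    arma::vec w = arma::solve(B, A.col(j_enter));
    double t_best = std::isfinite(u[j_enter]) ? u[j_enter] : R_PosInf;
    int leave = -1;  // -1 = bound flip of the entering variable
    for (int i = 0; i < m; ++i) {
      const double wi = sgn * w[i];
      const int bi = basis[i];
      if (wi > tol) {
        const double ti = x[bi] / wi;
        if (ti < t_best - tol ||
            (ti < t_best + tol && leave >= 0 &&
             bi < (int)basis[leave])) {
          t_best = ti; leave = i;
        }
      } else if (wi < -tol && std::isfinite(u[bi])) {
        const double ti = (u[bi] - x[bi]) / (-wi);
        if (ti < t_best - tol ||
            (ti < t_best + tol && leave >= 0 &&
             bi < (int)basis[leave])) {
          t_best = ti; leave = i;
        }
      }
    }
    if (!std::isfinite(t_best)) { status = 1; break; }
    if (t_best < 0) t_best = 0;
    x[j_enter] += sgn * t_best;
    for (int i = 0; i < m; ++i) x[basis[i]] -= sgn * w[i] * t_best;
    if (leave < 0) {
      at_upper[j_enter] = !at_upper[j_enter];
    } else {
      const int bl = basis[leave];
      const double wl = sgn * w[leave];
      at_upper[bl] = wl < 0;
      x[bl] = at_upper[bl] ? u[bl] : 0.0;
      in_basis[bl] = false;
      basis[leave] = j_enter;
      in_basis[j_enter] = true;
      at_upper[j_enter] = false;
    }
  }
  if (status == 2) stop("simplex: iteration limit reached");

  IntegerVector basis_out(m);
  for (int i = 0; i < m; ++i) basis_out[i] = basis[i] + 1;
  LogicalVector atu(n);
  for (int j = 0; j < n; ++j) atu[j] = at_upper[j];
  return List::create(_["status"] = status,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["basis"] = basis_out, _["at_upper"] = atu);
}
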