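#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with step set {(1,0),(0,1),(1,1)} and absolute
// amplitude difference as the local cost.  Backtracking prefers the
// diagonal predecessor, then (i-1,j), then (i,j-1), so the path is
// deterministic under ties.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("dtw: series must be non-empty");
  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::abs(a[i] - b[j]);
      if (i == 0 && j == 0) D(i, j) = c;
      else {
        double best = R_PosInf;
        if (i > 0 && j > 0) best = std::min(best, D(i - 1, j - 1));
        if (i > 0) best = std::min(best, D(i - 1, j));
        if (j > 0) best = std::min(best, D(i, j - 1));
        D(i, j) = c + best;
      }
    }
  }
  // backtrack
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double d = D(i - 1, j - 1), u = D(i - 1, j), l = D(i, j - 1);
      if (d <= u && d <= l) { --i; --j; }
      else if (u <= l) { --i; }
      else { --j; }
    } else if (i > 0) { --i; }
    else { --j; }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  const int len = pi.size();
  IntegerMatrix path(len, 2);
  for (int k = 0; k < len; ++k) {            // reverse to start at (1,1)
    path(k, 0) = pi[len - 1 - k];
    path(k, 1) = pj[len - 1 - k];
  }
  return List::create(_["cost"] = D(n - 1, m - 1), _["path"] = path);
}

// One cyclic coordinate-descent pass structure for the LASSO loss
//   (1/2N) sum_i (y_i - x_i' beta)^2 + lambda sum_j |beta_j|
// on centered data (intercept handled by the caller).  Residual r = y - X b
// is maintained; soft-thresholding update per coordinate.
static void cd_solve(const NumericMatrix& X, const NumericVector& y,
                     double lambda, std::vector<double>& beta,
                     std::vector<double>& r, const std::vector<double>& cj,
                     double tol, int max_sweeps, int& sweeps_used) {
  const int n = X.nrow(), p = X.ncol();
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      if (cj[j] <= 0.0) { continue; }        // constant column
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
      rho = rho / n + cj[j] * beta[j];
      double bnew;
      if (rho > lambda) bnew = (rho - lambda) / cj[j];
      else if (rho < -lambda) bnew = (rho + lambda) / cj[j];
      else bnew = 0.0;
      double diff = bnew - beta[j];
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= diff * X(i, j);
        beta[j] = bnew;
        max_change = std::max(max_change, std::abs(diff));
      }
    }
    if (max_change < tol) { sweeps_used = sweep + 1; return; }
  }
  sweeps_used = -1;                          // did not converge
}

// [[Rcpp::export(name = ".lasso_cd")]]
List lasso_cd(NumericMatrix Xc, NumericVector yc, double lambda,
              NumericVector beta_init, double tol = 1e-7,
              int max_sweeps = 100000) {
  const int n = Xc.nrow(), p = Xc.ncol();
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> r(yc.begin(), yc.end());
  std::vector<double> cj(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) { s += Xc(i, j) * Xc(i, j); r[i] -= 0.0; }
    cj[j] = s / n;
  }
  for (int j = 0; j < p; ++j)
    if (beta[j] != 0.0)
      for (int i = 0; i < n; ++i) r[i] -= beta[j] * Xc(i, j);
  int used = 0;
  cd_solve(Xc, yc, lambda, beta, r, cj, tol, max_sweeps, used);
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["converged"] = used >= 0,
                      _["sweeps"] = used);
}

// Warm-started solution path over a decreasing lambda sequence.
// [[Rcpp::export(name = ".lasso_path_cd")]]
List lasso_path_cd(NumericMatrix Xc, NumericVector yc,
                   NumericVector lambdas, double tol = 1e-7,
                   int max_sweeps = 100000) {
  const int n = Xc.nrow(), p = Xc.ncol(), nl = lambdas.size();
  std::vector<double> beta(p, 0.0), r(yc.begin(), yc.end()), cj(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Xc(i, j) * Xc(i, j);
    cj[j] = s / n;
  }
  NumericMatrix B(p, nl);
  LogicalVector conv(nl);
  for (int l = 0; l < nl; ++l) {
    int used = 0;
    cd_solve(Xc, yc, lambdas[l], beta, r, cj, tol, max_sweeps, used);
    conv[l] = used >= 0;
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
  }
  return List::create(_["beta"] = B, _["converged"] = conv);
}
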