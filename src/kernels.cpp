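#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system M x = rhs.
// lower/upper have length n-1 (sub/super diagonal), diag length n.
// [[Rcpp::export]]
NumericVector thomas_solve_cpp(NumericVector lower, NumericVector diag,
                               NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  if (lower.size() != n - 1 || upper.size() != n - 1 || rhs.size() != n)
    stop("inconsistent tridiagonal dimensions");
  std::vector<double> cp(n - 1), dp(n);
  double piv = diag[0];
  if (piv == 0.0) stop("zero pivot in tridiagonal solve");
  if (n > 1) cp[0] = upper[0] / piv;
  dp[0] = rhs[0] / piv;
  for (int i = 1; i < n; ++i) {
    piv = diag[i] - lower[i - 1] * cp[i - 1];
    if (piv == 0.0) stop("zero pivot in tridiagonal solve");
    if (i < n - 1) cp[i] = upper[i] / piv;
    dp[i] = (rhs[i] - lower[i - 1] * dp[i - 1]) / piv;
  }
  NumericVector x(n);
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}

// One Crank-Nicolson diffusion update: solves M a' = N a for a field a.
// [[Rcpp::export]]
NumericVector cn_step_cpp(NumericVector lowerM, NumericVector diagM,
                          NumericVector upperM, NumericVector lowerN,
                          NumericVector diagN, NumericVector upperN,
                          NumericVector a) {
  int n = a.size();
  NumericVector rhs(n);
  for (int i = 0; i < n; ++i) {
    double v = diagN[i] * a[i];
    if (i > 0) v += lowerN[i - 1] * a[i - 1];
    if (i < n - 1) v += upperN[i] * a[i + 1];
    rhs[i] = v;
  }
  return thomas_solve_cpp(lowerM, diagM, upperM, rhs);
}
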