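#include <Rcpp.h>
using namespace Rcpp;

// O(n) direct solve of a tridiagonal system by forward elimination /
// back substitution. Bands follow the usual convention: `lower` and
// `upper` have length n - 1 and sit immediately below / above `diag`.
// [[Rcpp::export]]
NumericVector thomas_solve_cpp(NumericVector lower, NumericVector diag,
                               NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  if (n < 1) stop("empty tridiagonal system");
  if (lower.size() != n - 1 || upper.size() != n - 1 || rhs.size() != n)
    stop("inconsistent band lengths for an order-%d tridiagonal system", n);

  std::vector<double> cp(n), dp(n);
  double piv = diag[0];
  if (piv == 0.0) stop("singular tridiagonal system: zero pivot at row 1");
  cp[0] = (n > 1) ? upper[0] / piv : 0.0;
  dp[0] = rhs[0] / piv;
  for (int i = 1; i < n; ++i) {
    piv = diag[i] - lower[i - 1] * cp[i - 1];
    if (piv == 0.0)
      stop("singular tridiagonal system: zero pivot at row %d", i + 1);
    cp[i] = (i < n - 1) ? upper[i] / piv : 0.0;
    dp[i] = (rhs[i] - lower[i - 1] * dp[i - 1]) / piv;
  }
  NumericVector x(n);
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}

// Backward-Euler / Picard time stepping for the 1-D Fisher-Kolmogorov
// equation on a uniform grid with zero-flux (mirrored ghost node)
// boundaries. The reaction term lambda*C*(1 - C/K) is linearised by
// lagging only the quadratic factor: each Picard sweep solves
//   (I + r*A - dt*lambda*(1 - C_prev/K)) C_new = C_old,
// which is tridiagonal; sweeps stop when max|C_new - C_prev| < eps.
// Profiles are recorded at the requested step indices (0 = initial
// condition). Returns the snapshot matrix plus Picard diagnostics.
// [[Rcpp::export]]
List fk_solve_cpp(NumericVector c_init, double D, double lambda, double K,
                  double dx, double dt, double eps, int max_picard_iters,
                  IntegerVector out_steps) {
  int n = c_init.size();
  if (n < 3) stop("grid must have at least 3 nodes");
  int n_out = out_steps.size();
  int n_steps = 0;
  for (int j = 0; j < n_out; ++j) {
    if (out_steps[j] < 0) stop("output steps must be nonnegative");
    if (j > 0 && out_steps[j] < out_steps[j - 1])
      stop("output steps must be sorted");
    if (out_steps[j] > n_steps) n_steps = out_steps[j];
  }

  double r = D * dt / (dx * dx);
  NumericMatrix out(n, n_out);
  IntegerVector picard_iters(n_out > 0 ? n_steps : 0);
  if ((int) picard_iters.size() != n_steps) picard_iters = IntegerVector(n_steps);

  std::vector<double> c_old(n), c_prev(n), c_new(n);
  std::vector<double> cp(n), dp(n), diag(n), rhs(n);
  for (int i = 0; i < n; ++i) c_old[i] = c_init[i];

  int jout = 0;
  while (jout < n_out && out_steps[jout] == 0) {
    for (int i = 0; i < n; ++i) out(i, jout) = c_old[i];
    ++jout;
  }

  for (int m = 1; m <= n_steps; ++m) {
    for (int i = 0; i < n; ++i) c_prev[i] = c_old[i];
    int iter = 0;
    while (true) {
      ++iter;
      // assemble: diag = 1 + 2r - dt*lambda*(1 - c_prev/K); off-diag -r,
      // with the boundary rows using -2r for the mirrored ghost node.
      for (int i = 0; i < n; ++i) {
        diag[i] = 1.0 + 2.0 * r - dt * lambda * (1.0 - c_prev[i] / K);
        rhs[i] = c_old[i];
      }
      // Thomas sweep inlined (bands are implicit: lower/upper = -r,
      // except upper[0] = lower[n-2] = -2r).
      double piv = diag[0];
      if (piv == 0.0) stop("singular system in implicit step %d", m);
      cp[0] = -2.0 * r / piv;
      dp[0] = rhs[0] / piv;
      for (int i = 1; i < n; ++i) {
        double lo = (i == n - 1) ? -2.0 * r : -r;
        piv = diag[i] - lo * cp[i - 1];
        if (piv == 0.0) stop("singular system in implicit step %d", m);
        cp[i] = (i < n - 1) ? -r / piv : 0.0;
        dp[i] = (rhs[i] - lo * dp[i - 1]) / piv;
      }
      c_new[n - 1] = dp[n - 1];
      for (int i = n - 2; i >= 0; --i) c_new[i] = dp[i] - cp[i] * c_new[i + 1];

      double delta = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = std::abs(c_new[i] - c_prev[i]);
        if (d > delta) delta = d;
      }
      std::swap(c_prev, c_new);
      if (delta < eps) break;
      if (iter >= max_picard_iters)
        stop("Picard iteration failed to converge within %d iterations at "
             "step %d (t = %g): last max-norm change %g exceeds tolerance %g",
             max_picard_iters, m, m * dt, delta, eps);
    }
    picard_iters[m - 1] = iter;
    std::swap(c_old, c_prev);
    while (jout < n_out && out_steps[jout] == m) {
      for (int i = 0; i < n; ++i) out(i, jout) = c_old[i];
      ++jout;
    }
  }

  return List::create(_["profiles"] = out,
                      _["picard_iters"] = picard_iters,
                      _["n_steps"] = n_steps);
}
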