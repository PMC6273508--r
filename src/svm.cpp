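#include <Rcpp.h>
using namespace Rcpp;

// Generic SMO solver for the SVM dual
//   min_a  1/2 a' Q a + p' a   s.t.  y' a = 0,  0 <= a_i <= C_i
// with Q_ij = y_i y_j K_ij. First-order (maximal violating pair) working-set
// selection and the standard pairwise analytic update; this is the dual form
// shared by weighted C-SVC (p = -1, y = labels) and eps-SVR (extended 2n
// problem with sign vector y and p_i = eps -/+ y_i). Returns alpha, rho and
// the number of iterations. rho is defined so the decision function is
//   f(x) = sum_i a_i y_i K(x_i, x) - rho.
// [[Rcpp::export]]
List cpp_smo_solve(NumericMatrix K, NumericVector y, NumericVector p,
                   NumericVector C, double tol, int max_iter) {
  const int n = K.nrow();
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0), G(p.begin(), p.end());
  const double *Kd = K.begin();  // column-major; K is symmetric

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working set: i = argmax_{t in I_up} -y_t G_t ; j = argmin_{t in I_low}
    int i = -1, j = -1;
    double gmax = -INFINITY, gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      const double yg = -y[t] * G[t];
      const bool up = (y[t] > 0) ? (alpha[t] < C[t]) : (alpha[t] > 0);
      const bool lo = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C[t]);
      if (up && yg > gmax) { gmax = yg; i = t; }
      if (lo && yg < gmin) { gmin = yg; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    const double Ci = C[i], Cj = C[j];
    const double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > Ci - Cj) { if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = Ci - diff; } }
      else                { if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = Cj + diff; } }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > Ci) { if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = sum - Ci; } }
      else          { if (alpha[j] < 0)  { alpha[j] = 0;  alpha[i] = sum; } }
      if (sum > Cj) { if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = sum - Cj; } }
      else          { if (alpha[i] < 0)  { alpha[i] = 0;  alpha[j] = sum; } }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;
    const double ci = y[i] * dai, cj = y[j] * daj;
    const double *Ki = Kd + (size_t)i * n, *Kj = Kd + (size_t)j * n;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (ci * Ki[t] + cj * Kj[t]);
  }

  // rho from the KKT conditions (mean y_t G_t over free points, else midpoint)
  double ub = INFINITY, lb = -INFINITY, sum_free = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    const double yg = y[t] * G[t];
    if (alpha[t] >= C[t] - 1e-12) { if (y[t] < 0) ub = std::min(ub, yg); else lb = std::max(lb, yg); }
    else if (alpha[t] <= 1e-12)   { if (y[t] > 0) ub = std::min(ub, yg); else lb = std::max(lb, yg); }
    else { ++nfree; sum_free += yg; }
  }
  const double rho = nfree > 0 ? sum_free / nfree : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iter"] = iter,
                      _["converged"] = iter < max_iter);
}
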