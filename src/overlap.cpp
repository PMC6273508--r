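#include <Rcpp.h>
using namespace Rcpp;

// First-order Gaussian overlap volume between two atom-centred Gaussian
// densities rho(r) = sum_i p_i exp(-a_i |r - c_i|^2):
//   V_AB = sum_{i,j} p_i p_j (pi/(a_i+a_j))^{3/2} exp(-(a_i a_j/(a_i+a_j)) d_ij^2)
// which is the exact integral of rho_A * rho_B. Coordinates are assumed
// already posed; the caller applies any rigid transform beforehand.
static double pair_overlap(const double *ca, int na, const double *aa, const double *pa,
                           const double *cb, int nb, const double *ab, const double *pb) {
  const double PI = 3.14159265358979323846;
  double v = 0.0;
  for (int i = 0; i < na; ++i) {
    const double xi = ca[i], yi = ca[i + na], zi = ca[i + 2 * na];
    const double ai = aa[i], pi_ = pa[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - cb[j], dy = yi - cb[j + nb], dz = zi - cb[j + 2 * nb];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double s = ai + ab[j];
      const double e = ai * ab[j] / s * d2;
      if (e > 34.0) continue;
      v += pi_ * pb[j] * std::pow(PI / s, 1.5) * std::exp(-e);
    }
  }
  return v;
}

// [[Rcpp::export]]
double cpp_gaussian_overlap(NumericMatrix ca, NumericVector aa, NumericVector pa,
                            NumericMatrix cb, NumericVector ab, NumericVector pb) {
  const int na = ca.nrow(), nb = cb.nrow();
  const double PI = 3.14159265358979323846;
  double v = 0.0;
  for (int i = 0; i < na; ++i) {
    const double xi = ca(i, 0), yi = ca(i, 1), zi = ca(i, 2);
    const double ai = aa[i], pi_ = pa[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - cb(j, 0), dy = yi - cb(j, 1), dz = zi - cb(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double s = ai + ab[j];
      const double k = ai * ab[j] / s;
      // negligible beyond ~30 in the exponent
      const double e = k * d2;
      if (e > 34.0) continue;
      v += pi_ * pb[j] * std::pow(PI / s, 1.5) * std::exp(-e);
    }
  }
  return v;
}

// Combined shape + feature score of a posed query against a rigid template,
// evaluated in one call for the Nelder-Mead refinement loop. The pose is
// R = expmap(par[0:2]) %*% R0, t = t0 + par[3:5], applied to the query.
// Feature point sets arrive as parallel lists (one matrix per type; a
// 0-row matrix means the type is absent in that molecule); all feature
// Gaussians share one alpha/amplitude (fixed 1.0 A radius).
// [[Rcpp::export]]
double cpp_pose_score(NumericMatrix tc, NumericVector ta, NumericVector tp,
                      double tself,
                      NumericMatrix qc, NumericVector qa, NumericVector qp,
                      double qself,
                      List tfeat, List qfeat,
                      NumericVector tfeat_self, NumericVector qfeat_self,
                      double feat_alpha, double feat_amp,
                      double w_shape, NumericVector par,
                      NumericMatrix R0, NumericVector t0) {
  // rotation matrix from exponential map composed with R0
  double R[9];
  {
    const double vx = par[0], vy = par[1], vz = par[2];
    const double th = std::sqrt(vx * vx + vy * vy + vz * vz);
    double E[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    if (th > 1e-12) {
      const double ax = vx / th, ay = vy / th, az = vz / th;
      const double c = std::cos(th), s = std::sin(th), C = 1 - c;
      E[0] = c + ax * ax * C;      E[1] = ax * ay * C - az * s; E[2] = ax * az * C + ay * s;
      E[3] = ay * ax * C + az * s; E[4] = c + ay * ay * C;      E[5] = ay * az * C - ax * s;
      E[6] = az * ax * C - ay * s; E[7] = az * ay * C + ax * s; E[8] = az * az * C + ay * 0;
      E[8] = c + az * az * C;
    }
    // R = E %*% R0 (row-major E, R0 is an R matrix: column-major)
    for (int r = 0; r < 3; ++r)
      for (int cidx = 0; cidx < 3; ++cidx)
        R[3 * r + cidx] = E[3 * r + 0] * R0(0, cidx) +
                          E[3 * r + 1] * R0(1, cidx) +
                          E[3 * r + 2] * R0(2, cidx);
  }
  const double tx = t0[0] + par[3], ty = t0[1] + par[4], tz = t0[2] + par[5];

  const int nq = qc.nrow();
  std::vector<double> qt(3 * nq);
  for (int i = 0; i < nq; ++i) {
    const double x = qc(i, 0), y = qc(i, 1), z = qc(i, 2);
    qt[i]          = R[0] * x + R[1] * y + R[2] * z + tx;
    qt[i + nq]     = R[3] * x + R[4] * y + R[5] * z + ty;
    qt[i + 2 * nq] = R[6] * x + R[7] * y + R[8] * z + tz;
  }

  const double vab = pair_overlap(tc.begin(), tc.nrow(), ta.begin(), tp.begin(),
                                  qt.data(), nq, qa.begin(), qp.begin());
  const double shape = vab / (tself + qself - vab);

  double feat = 1.0;
  const int ntypes = tfeat.size();
  if (ntypes > 0) {
    double acc = 0.0;
    std::vector<double> al, am, buf;
    for (int k = 0; k < ntypes; ++k) {
      NumericMatrix tm = tfeat[k], qm = qfeat[k];
      const int ntm = tm.nrow(), nqm = qm.nrow();
      if (ntm == 0 || nqm == 0) { continue; }  // one side absent: score 0
      buf.assign(3 * nqm, 0.0);
      for (int i = 0; i < nqm; ++i) {
        const double x = qm(i, 0), y = qm(i, 1), z = qm(i, 2);
        buf[i]           = R[0] * x + R[1] * y + R[2] * z + tx;
        buf[i + nqm]     = R[3] * x + R[4] * y + R[5] * z + ty;
        buf[i + 2 * nqm] = R[6] * x + R[7] * y + R[8] * z + tz;
      }
      if ((int)al.size() < std::max(ntm, nqm)) {
        al.assign(std::max(ntm, nqm), feat_alpha);
        am.assign(std::max(ntm, nqm), feat_amp);
      }
      const double fab = pair_overlap(tm.begin(), ntm, al.data(), am.data(),
                                      buf.data(), nqm, al.data(), am.data());
      acc += fab / (tfeat_self[k] + qfeat_self[k] - fab);
    }
    feat = acc / ntypes;
  }
  return w_shape * shape + (1 - w_shape) * feat;
}
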