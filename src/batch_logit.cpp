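#include <Rcpp.h>
using namespace Rcpp;

// Batched IRLS for k logistic models over the same rows; model j is
// y ~ 1 + F(,j) + pd. Returns the two-sided Wald p-value of the feature
// coefficient per model, NA where a model failed to converge or
// (quasi-)separated. Hot loop of the global permutation test.
// [[Rcpp::export]]
NumericVector cpp_batch_feature_wald(NumericVector y, NumericMatrix F,
                                     NumericVector pd, int maxit = 25,
                                     double tol = 1e-8) {
  const int n = y.size(), k = F.ncol();
  NumericVector out(k);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  if (ybar < 1e-6) ybar = 1e-6;
  if (ybar > 1 - 1e-6) ybar = 1 - 1e-6;
  const double b0_start = std::log(ybar / (1.0 - ybar));

  for (int j = 0; j < k; ++j) {
    double b0 = b0_start, b1 = 0.0, b2 = 0.0;
    bool conv = false;
    double i22 = NA_REAL;
    for (int it = 0; it < maxit; ++it) {
      double s11 = 0, s1f = 0, s1p = 0, sff = 0, sfp = 0, spp = 0;
      double t1 = 0, tf = 0, tp = 0;
      for (int i = 0; i < n; ++i) {
        const double f = F(i, j), q = pd[i];
        const double eta = b0 + b1 * f + b2 * q;
        const double mu = 1.0 / (1.0 + std::exp(-eta));
        double w = mu * (1.0 - mu);
        if (w < 1e-10) w = 1e-10;
        const double z = eta + (y[i] - mu) / w;
        s11 += w; s1f += w * f; s1p += w * q;
        sff += w * f * f; sfp += w * f * q; spp += w * q * q;
        t1 += w * z; tf += w * f * z; tp += w * z * q;
      }
      const double det = s11 * (sff * spp - sfp * sfp) -
        s1f * (s1f * spp - sfp * s1p) + s1p * (s1f * sfp - sff * s1p);
      if (det == 0.0 || !std::isfinite(det)) { conv = false; break; }
      const double i11 = (sff * spp - sfp * sfp) / det;
      const double i12 = (sfp * s1p - s1f * spp) / det;
      const double i13 = (s1f * sfp - sff * s1p) / det;
      i22 = (s11 * spp - s1p * s1p) / det;
      const double i23 = (s1f * s1p - s11 * sfp) / det;
      const double i33 = (s11 * sff - s1f * s1f) / det;
      const double n0 = i11 * t1 + i12 * tf + i13 * tp;
      const double n1 = i12 * t1 + i22 * tf + i23 * tp;
      const double n2 = i13 * t1 + i23 * tf + i33 * tp;
      const double del = std::max(std::max(std::fabs(n0 - b0),
                                           std::fabs(n1 - b1)),
                                  std::fabs(n2 - b2)) /
        (1.0 + std::max(std::max(std::fabs(b0), std::fabs(b1)),
                        std::fabs(b2)));
      b0 = n0; b1 = n1; b2 = n2;
      if (del < tol) { conv = true; break; }
    }
    const double se1 = std::sqrt(i22);
    const double bmax = std::max(std::max(std::fabs(b0), std::fabs(b1)),
                                 std::fabs(b2));
    const bool bad = !conv || !std::isfinite(se1) || !std::isfinite(b1) ||
      bmax > 30.0 || se1 > 100.0;
    out[j] = bad ? NA_REAL
                 : 2.0 * R::pnorm(-std::fabs(b1 / se1), 0.0, 1.0, 1, 0);
  }
  return out;
}
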