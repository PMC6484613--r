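#include <Rcpp.h>
using namespace Rcpp;

// One Metropolis scan over a transition's coefficient block.
// Proposals use the pre-drawn standard normals z and uniforms u so the
// update sequence is identical to the reference R implementation.
// [[Rcpp::export(name = ".beta_scan_cpp")]]
List beta_scan_cpp(NumericMatrix X, NumericVector bH, NumericVector lp,
                   NumericVector elp, NumericVector sxe, NumericVector beta,
                   NumericVector prior_sd2, NumericVector scales,
                   NumericVector z, NumericVector u) {
  int n = X.nrow(), p = X.ncol();
  NumericVector lp2 = clone(lp), elp2 = clone(elp), beta2 = clone(beta);
  IntegerVector acc(p);
  std::vector<double> newelp(n);
  double dll_total = 0.0;
  for (int j = 0; j < p; ++j) {
    double d = z[j] * scales[j];
    double s = 0.0;
    const double* xj = X.begin() + static_cast<R_xlen_t>(j) * n;
    for (int i = 0; i < n; ++i) {
      double ne = elp2[i] * std::exp(xj[i] * d);
      newelp[i] = ne;
      s += bH[i] * (ne - elp2[i]);
    }
    double dll = sxe[j] * d - s;
    double bj = beta2[j];
    double dlp = (bj * bj - (bj + d) * (bj + d)) / (2.0 * prior_sd2[j]);
    if (std::log(u[j]) < dll + dlp) {
      beta2[j] = bj + d;
      for (int i = 0; i < n; ++i) {
        lp2[i] += xj[i] * d;
        elp2[i] = newelp[i];
      }
      dll_total += dll;
      acc[j] = 1;
    }
  }
  return List::create(_["beta"] = beta2, _["lp"] = lp2, _["elp"] = elp2,
                      _["dll"] = dll_total, _["acc"] = acc);
}
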