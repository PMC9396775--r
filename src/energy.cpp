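#include <Rcpp.h>
using namespace Rcpp;

// Core potential of the 2D AB off-lattice chain.
// angles: n-2 interior bend angles; eta: n polarities (+1 A, -1 B).
// Returns (backbone, nonbonded, total); nonbonded is +Inf when any
// non-adjacent pair is closer than 1e-6 (diverging potential).
static void chain_energy_impl(const double* a, const double* eta, int n,
                              double* out) {
  std::vector<double> x(n), y(n);
  x[0] = 0.0; y[0] = 0.0;
  x[1] = 1.0; y[1] = 0.0;
  double theta = 0.0;
  for (int k = 2; k < n; ++k) {
    theta += a[k - 2];
    x[k] = x[k - 1] + std::cos(theta);
    y[k] = y[k - 1] + std::sin(theta);
  }
  double e1 = 0.0;
  for (int i = 0; i < n - 2; ++i) e1 += 0.25 * (1.0 - std::cos(a[i]));
  double e2 = 0.0;
  bool diverged = false;
  for (int i = 0; i < n - 2 && !diverged; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double r2 = dx * dx + dy * dy;
      if (r2 < 1e-12) { diverged = true; break; }
      double C = (1.0 + eta[i] + eta[j] + 5.0 * eta[i] * eta[j]) / 8.0;
      double ir6 = 1.0 / (r2 * r2 * r2);
      e2 += 4.0 * (ir6 * ir6 - C * ir6);
    }
  }
  if (diverged) e2 = R_PosInf;
  out[0] = e1;
  out[1] = e2;
  out[2] = e1 + e2;
}

// [[Rcpp::export]]
NumericVector chain_energy_cpp(NumericVector angles, NumericVector eta) {
  int n = eta.size();
  if (n < 3) stop("need n >= 3 residues");
  if (angles.size() != n - 2) stop("angle vector must have length n - 2");
  NumericVector out(3);
  chain_energy_impl(angles.begin(), eta.begin(), n, out.begin());
  out.names() = CharacterVector::create("backbone", "nonbonded", "total");
  return out;
}

// [[Rcpp::export]]
NumericVector chain_energy_batch_cpp(NumericMatrix positions,
                                     NumericVector eta) {
  int n = eta.size();
  int m = positions.nrow();
  if (positions.ncol() != n - 2) stop("positions must have n - 2 columns");
  NumericVector totals(m);
  std::vector<double> row(n - 2);
  double out[3];
  for (int p = 0; p < m; ++p) {
    for (int d = 0; d < n - 2; ++d) row[d] = positions(p, d);
    chain_energy_impl(row.data(), eta.begin(), n, out);
    totals[p] = out[2];
  }
  return totals;
}
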