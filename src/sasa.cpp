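#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area on heavy atoms.
// Test points are placed on a deterministic golden-section spiral so that
// results are reproducible for a given n_points.

// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector vdw, double probe,
                       int n_points) {
  const int n = xyz.nrow();
  NumericVector out(n);
  if (n == 0) return out;

  // golden spiral unit sphere
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    sx[k] = r * std::cos(th);
    sy[k] = r * std::sin(th);
    sz[k] = z;
  }

  std::vector<double> rad(n);
  for (int i = 0; i < n; ++i) rad[i] = vdw[i] + probe;

  // neighbour lists via simple cutoff scan (n is a few thousand at most)
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double lim = rad[i] + rad[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xyz(i, 0) + rad[i] * sx[k];
      double py = xyz(i, 1) + rad[i] * sy[k];
      double pz = xyz(i, 2) + rad[i] * sz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = px - xyz(j, 0);
        double dy = py - xyz(j, 1);
        double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rad[j] * rad[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * rad[i] * rad[i] * acc / n_points;
  }
  return out;
}
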