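#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// Test points are placed on each atom's solvent-expanded sphere
// (radius r_i + probe) with a golden-spiral lattice; a point is
// accessible when it lies outside every neighbouring atom's expanded
// sphere. ASA_i = 4*pi*(r_i+probe)^2 * accessible fraction.

// [[Rcpp::export]]
NumericVector sasa_atoms(NumericMatrix xyz, NumericVector radii,
                         double probe = 1.4, int n_points = 960) {
  const int n = xyz.nrow();
  if (radii.size() != n) stop("radii length must match atom count");
  if (n_points < 4) stop("n_points must be >= 4");

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    px[k] = rk * std::cos(th);
    py[k] = rk * std::sin(th);
    pz[k] = zk;
  }

  NumericVector asa(n);
  std::vector<int> nb;
  nb.reserve(256);
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double rj = radii[j] + probe;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      const double cut = ri + rj;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double qx = xi + ri * px[k];
      const double qy = yi + ri * py[k];
      const double qz = zi + ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double rj = radii[j] + probe;
        const double dx = qx - xyz(j, 0), dy = qy - xyz(j, 1), dz = qz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    asa[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)n_points;
  }
  return asa;
}
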