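#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
//
// Each atom is inflated by the probe radius and covered with a fixed
// deterministic Fibonacci lattice of sample points; a point is exposed when
// it lies outside every neighbouring inflated sphere.  The point set depends
// only on n_points, so results are identical run to run and machine to
// machine (pure double arithmetic, no RNG).

// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe = 1.4, int n_points = 960) {
  const int n = xyz.nrow();
  if (radii.size() != n) stop("radii length must match atom count");
  if (n_points < 12) stop("n_points too small");

  // Fibonacci sphere lattice (unit sphere)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));  // golden angle
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }

  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  NumericVector out(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      double lim = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double sx = xi + R[i] * px[k];
      double sy = yi + R[i] * py[k];
      double sz = zi + R[i] * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = sx - xyz(j, 0), dy = sy - xyz(j, 1), dz = sz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) { free_pt = false; break; }
      }
      if (free_pt) ++exposed;
    }
    out[i] = 4.0 * M_PI * R[i] * R[i] * exposed / n_points;
  }
  return out;
}
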