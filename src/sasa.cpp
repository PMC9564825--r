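#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
//
// For each atom, quasi-uniform test points are placed on a sphere of radius
// r_vdw + probe; the accessible fraction (points not inside any neighbor's
// expanded sphere) times the sphere area gives the atom's SASA.
//
// xyz:       n x 3 coordinates (Angstrom)
// radii:     n van der Waals radii (Angstrom)
// probe:     probe radius (Angstrom)
// sphere:    m x 3 unit-sphere test points
// [[Rcpp::export(name = ".sasa_kernel")]]
NumericVector sasa_kernel(NumericMatrix xyz, NumericVector radii,
                          double probe, NumericMatrix sphere) {
  const int n = xyz.nrow(), m = sphere.nrow();
  NumericVector area(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);

  std::vector<double> ex(n);
  for (int i = 0; i < n; ++i) ex[i] = radii[i] + probe;

  std::vector<int> nb;
  nb.reserve(256);
  for (int i = 0; i < n; ++i) {
    const double Ri = ex[i];
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nb.clear();
    const double reach = Ri + rmax + probe;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double lim = Ri + ex[j];
      if (d2 < lim * lim && d2 < reach * reach) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < m; ++p) {
      const double px = xi + Ri * sphere(p, 0);
      const double py = yi + Ri * sphere(p, 1);
      const double pz = zi + Ri * sphere(p, 2);
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = px - xyz(j, 0), dy = py - xyz(j, 1),
                     dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < ex[j] * ex[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)m;
  }
  return area;
}
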