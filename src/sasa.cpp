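#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley accessible surface area, one probe-expanded sphere per atom.
// Test points are a deterministic golden-angle spiral, so results are exactly
// reproducible for a fixed (coords, radii, probe, n_points).
// [[Rcpp::export(name = ".sr_atom_areas")]]
NumericVector sr_atom_areas(NumericMatrix coords, NumericVector radii,
                            double probe, int n_points) {
  const int n = coords.nrow();
  if (n == 0) stop("no atoms");
  NumericVector out(n);

  // unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }

  std::vector<double> er(n); // expanded radii
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = er[i];
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double lim = ri + er[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double sx = xi + ri * px[k], sy = yi + ri * py[k],
                   sz = zi + ri * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int j = nbr[m];
        double dx = sx - coords(j, 0), dy = sy - coords(j, 1),
               dz = sz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)n_points;
  }
  return out;
}

// Minimum distance from each row-group of A to the point set B.
// groups: 0-based group index per row of A, n_groups total.
// [[Rcpp::export(name = ".group_min_dist")]]
NumericVector group_min_dist(NumericMatrix a, IntegerVector groups,
                             int n_groups, NumericMatrix b) {
  NumericVector out(n_groups, R_PosInf);
  const int na = a.nrow(), nb = b.nrow();
  for (int i = 0; i < na; ++i) {
    const int g = groups[i];
    double best = out[g];
    const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = b(j, 0) - xi, dy = b(j, 1) - yi, dz = b(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best * best) best = std::sqrt(d2);
    }
    out[g] = best;
  }
  return out;
}
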