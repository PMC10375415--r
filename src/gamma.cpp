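// Discrete gamma-index map: for each reference voxel the minimum of
// Gamma(e, r) = sqrt(dDose^2 / dD^2 + dist^2 / dd^2) over evaluated
// voxels within a search radius. Offsets are visited in order of
// increasing distance so the scan can stop as soon as the distance term
// alone exceeds the running minimum, which makes the restriction exact.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Off { int dx, dy, dz; double d2; };

// [[Rcpp::export]]
NumericVector cpp_gamma_map(NumericVector ref, NumericVector eval,
                            IntegerVector dims, double voxel_mm,
                            double dD_abs, double dd_mm,
                            double radius_mm) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int rv = (int)std::floor(radius_mm / voxel_mm + 1e-9);
  std::vector<Off> offs;
  for (int dz = -rv; dz <= rv; ++dz)
    for (int dy = -rv; dy <= rv; ++dy)
      for (int dx = -rv; dx <= rv; ++dx) {
        double d2 = (double)(dx * dx + dy * dy + dz * dz) * voxel_mm *
          voxel_mm;
        if (d2 <= radius_mm * radius_mm + 1e-9)
          offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off& a, const Off& b) { return a.d2 < b.d2; });
  NumericVector out(ref.size());
  const double* R = REAL(ref);
  const double* E = REAL(eval);
  double dd2 = dd_mm * dd_mm, dD2 = dD_abs * dD_abs;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        double rr = R[ix + nx * (iy + ny * iz)];
        double best = 1e300;
        for (const Off& o : offs) {
          double dterm = o.d2 / dd2;
          if (dterm >= best) break;
          int jx = ix + o.dx, jy = iy + o.dy, jz = iz + o.dz;
          if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny ||
              jz >= nz)
            continue;
          double dd = E[jx + nx * (jy + ny * jz)] - rr;
          double g2 = dd * dd / dD2 + dterm;
          if (g2 < best) best = g2;
        }
        out[ix + nx * (iy + ny * iz)] = std::sqrt(best);
      }
  return out;
}
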