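#include <Rcpp.h>
using namespace Rcpp;

// PCIT edge elimination. For every trio (x, y, z) the three first-order
// partial correlations are computed; the trio tolerance is the mean of
// the partial/direct ratios,
//   eps = (r_xy.z/r_xy + r_xz.y/r_xz + r_yz.x/r_yz) / 3,
// and the edge x-y is eliminated if, for some z,
//   |r_xy| <= |eps * r_xz| and |r_xy| <= |eps * r_yz|   (compare = 0)
// or, in the alternative partial-comparison mode,
//   |r_xy.z| <= |eps * r_xz.y| and |r_xy.z| <= |eps * r_yz.x| (compare = 1).
// Trios with a unit-magnitude or zero direct correlation are skipped.
// [[Rcpp::export(name = ".pcit_keep")]]
LogicalMatrix pcit_keep(NumericMatrix R, int compare) {
  const int n = R.nrow();
  if (R.ncol() != n) stop("correlation matrix must be square");
  LogicalMatrix keep(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      keep(i, j) = (i != j) && (R(i, j) != 0.0);

  const double one = 1.0 - 1e-12;
  for (int z = 0; z < n; ++z) {
    for (int x = 0; x < n - 1; ++x) {
      if (x == z) continue;
      for (int y = x + 1; y < n; ++y) {
        if (y == z) continue;
        const double rxy = R(x, y), rxz = R(x, z), ryz = R(y, z);
        if (rxy == 0.0 || rxz == 0.0 || ryz == 0.0) continue;
        if (std::fabs(rxz) >= one || std::fabs(ryz) >= one ||
            std::fabs(rxy) >= one) continue;
        const double dxy = std::sqrt((1 - rxz * rxz) * (1 - ryz * ryz));
        const double dxz = std::sqrt((1 - rxy * rxy) * (1 - ryz * ryz));
        const double dyz = std::sqrt((1 - rxy * rxy) * (1 - rxz * rxz));
        const double pxy = (rxy - rxz * ryz) / dxy;
        const double pxz = (rxz - rxy * ryz) / dxz;
        const double pyz = (ryz - rxy * rxz) / dyz;
        const double eps = (pxy / rxy + pxz / rxz + pyz / ryz) / 3.0;
        bool drop;
        if (compare == 0)
          drop = std::fabs(rxy) <= std::fabs(eps * rxz) &&
                 std::fabs(rxy) <= std::fabs(eps * ryz);
        else
          drop = std::fabs(pxy) <= std::fabs(eps * pxz) &&
                 std::fabs(pxy) <= std::fabs(eps * pyz);
        if (drop) { keep(x, y) = false; keep(y, x) = false; }
      }
    }
  }
  return keep;
}
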