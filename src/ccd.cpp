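// Cyclic coordinate descent inner loop.
//
// The moving backbone is passed residue-major (N, CA, C per residue)
// followed by three ghost continuation atoms; every free torsion rotates
// a contiguous tail of that matrix.  Each torsion is set to the analytic
// angle minimizing the squared deviation of the ghost atoms from the
// fixed anchor triad (classic CCD update).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".ccd_cycles")]]
List ccd_cycles(NumericMatrix M_in, NumericMatrix target,
                IntegerMatrix tors, int grow, int max_cycles,
                double tolerance, double ideal_cn) {
  NumericMatrix M = clone(M_in);
  const int nrow = M.nrow();
  const int nt = tors.nrow();
  double gap = R_PosInf;
  int cycles = 0;

  for (int cyc = 1; cyc <= max_cycles; ++cyc) {
    cycles = cyc;
    for (int t = 0; t < nt; ++t) {
      const int a = tors(t, 0) - 1;
      const int b = tors(t, 1) - 1;
      const int from = tors(t, 2) - 1;
      const double px = M(a, 0), py = M(a, 1), pz = M(a, 2);
      double ux = M(b, 0) - px, uy = M(b, 1) - py, uz = M(b, 2) - pz;
      const double un = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (un < 1e-12) continue;
      ux /= un; uy /= un; uz /= un;

      double num = 0.0, den = 0.0;
      for (int j = 0; j < 3; ++j) {
        const int gj = grow + j;
        const double mx = M(gj, 0) - px, my = M(gj, 1) - py,
                     mz = M(gj, 2) - pz;
        const double proj = mx * ux + my * uy + mz * uz;
        const double ox = proj * ux, oy = proj * uy, oz = proj * uz;
        const double rx = mx - ox, ry = my - oy, rz = mz - oz;
        const double sx = uy * rz - uz * ry;
        const double sy = uz * rx - ux * rz;
        const double sz = ux * ry - uy * rx;
        const double dx = target(j, 0) - px - ox;
        const double dy = target(j, 1) - py - oy;
        const double dz = target(j, 2) - pz - oz;
        num += sx * dx + sy * dy + sz * dz;
        den += rx * dx + ry * dy + rz * dz;
      }
      if (std::fabs(num) < 1e-12 && std::fabs(den) < 1e-12) continue;
      const double theta = std::atan2(num, den);
      if (std::fabs(theta) < 1e-11) continue;
      const double ct = std::cos(theta), st = std::sin(theta);
      for (int r = from; r < nrow; ++r) {
        const double x = M(r, 0) - px, y = M(r, 1) - py,
                     z = M(r, 2) - pz;
        const double dot = x * ux + y * uy + z * uz;
        const double cx = uy * z - uz * y;
        const double cy = uz * x - ux * z;
        const double cz = ux * y - uy * x;
        const double f = (1.0 - ct) * dot;
        M(r, 0) = px + x * ct + cx * st + ux * f;
        M(r, 1) = py + y * ct + cy * st + uy * f;
        M(r, 2) = pz + z * ct + cz * st + uz * f;
      }
    }
    // closure deviation at the designated break: C(b) to anchor N
    const double ddx = M(grow - 1, 0) - target(0, 0);
    const double ddy = M(grow - 1, 1) - target(0, 1);
    const double ddz = M(grow - 1, 2) - target(0, 2);
    gap = std::fabs(std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz) -
                    ideal_cn);
    if (gap <= tolerance) break;
  }
  return List::create(_["M"] = M, _["gap"] = gap,
                      _["cycles"] = cycles);
}
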