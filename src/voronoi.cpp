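#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Capped 3D Voronoi tessellation of point seeds.
//
// Each cell is the intersection of the seed's Voronoi region with a sphere
// of radius cap_radius around the seed.  A cell-cell contact face lives on
// the bisector plane of the two seeds: it is the chord disc of the cap
// sphere clipped by the bisector half-planes of every other seed.  The disc
// boundary is approximated by an inscribed regular n_circle-gon (relative
// area error ~ 2*pi^2 / (3*n^2); < 1e-3 for n = 128), the half-plane
// clipping is exact (Sutherland-Hodgman).
//
// Cell volumes use the divergence theorem about the seed: planar faces at
// distance h contribute h*A/3, the residual spherical patch contributes
// R*A_sph/3 with A_sph estimated on a Fibonacci direction lattice.

namespace {

struct Pt2 { double a, b; };

double polyArea(const std::vector<Pt2>& p) {
  const int n = p.size();
  if (n < 3) return 0.0;
  double s = 0.0;
  for (int t = 0; t < n; ++t) {
    const Pt2& u = p[t];
    const Pt2& v = p[(t + 1) % n];
    s += u.a * v.b - v.a * u.b;
  }
  return std::fabs(s) * 0.5;
}

// keep region g0 + ga*a + gb*b >= 0
void clipHalfPlane(std::vector<Pt2>& poly, double g0, double ga, double gb,
                   std::vector<Pt2>& out) {
  out.clear();
  const int n = poly.size();
  if (n == 0) return;
  for (int t = 0; t < n; ++t) {
    const Pt2& cur = poly[t];
    const Pt2& nxt = poly[(t + 1) % n];
    const double fc = g0 + ga * cur.a + gb * cur.b;
    const double fn = g0 + ga * nxt.a + gb * nxt.b;
    if (fc >= 0) out.push_back(cur);
    if ((fc > 0 && fn < 0) || (fc < 0 && fn > 0)) {
      const double t01 = fc / (fc - fn);
      out.push_back({cur.a + t01 * (nxt.a - cur.a),
                     cur.b + t01 * (nxt.b - cur.b)});
    }
  }
  poly.swap(out);
}

} // namespace

// [[Rcpp::export(name = ".voronoi_capped_cpp")]]
List voronoi_capped_cpp(NumericMatrix pts, double cap_radius,
                        int n_circle = 128, int n_sphere = 1500,
                        bool volumes = true) {
  const int n = pts.nrow();
  const double R = cap_radius;
  const double R2 = R * R;

  // neighbour candidates: seeds closer than 2R
  std::vector< std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i,0) - pts(j,0), dy = pts(i,1) - pts(j,1),
             dz = pts(i,2) - pts(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < 1e-18)
        stop("duplicate seed positions at rows %d and %d", i + 1, j + 1);
      if (d2 < 4.0 * R2) { nbr[i].push_back(j); nbr[j].push_back(i); }
    }
  }

  std::vector<double> ca(n_circle), sa(n_circle);
  for (int t = 0; t < n_circle; ++t) {
    double ang = 2.0 * M_PI * (t + 0.5) / n_circle;
    ca[t] = std::cos(ang); sa[t] = std::sin(ang);
  }

  std::vector<int> ei, ej;
  std::vector<double> earea;
  std::vector<double> vol(n, 0.0);

  std::vector<Pt2> poly, scratch;
  poly.reserve(n_circle + 16); scratch.reserve(n_circle + 16);

  for (int i = 0; i < n; ++i) {
    for (size_t q = 0; q < nbr[i].size(); ++q) {
      int j = nbr[i][q];
      if (j < i) continue;
      double nx = pts(j,0) - pts(i,0), ny = pts(j,1) - pts(i,1),
             nz = pts(j,2) - pts(i,2);
      const double d = std::sqrt(nx*nx + ny*ny + nz*nz);
      nx /= d; ny /= d; nz /= d;
      const double rho2 = R2 - 0.25 * d * d;
      if (rho2 <= 0) continue;
      const double rho = std::sqrt(rho2);
      const double mx = 0.5 * (pts(i,0) + pts(j,0)),
                   my = 0.5 * (pts(i,1) + pts(j,1)),
                   mz = 0.5 * (pts(i,2) + pts(j,2));
      // orthonormal basis of the bisector plane
      double e1x, e1y, e1z;
      if (std::fabs(nx) < 0.9) { e1x = 0; e1y = -nz; e1z = ny; }
      else                     { e1x = -nz; e1y = 0; e1z = nx; }
      double e1n = std::sqrt(e1x*e1x + e1y*e1y + e1z*e1z);
      e1x /= e1n; e1y /= e1n; e1z /= e1n;
      const double e2x = ny*e1z - nz*e1y,
                   e2y = nz*e1x - nx*e1z,
                   e2z = nx*e1y - ny*e1x;

      poly.clear();
      for (int t = 0; t < n_circle; ++t)
        poly.push_back({rho * ca[t], rho * sa[t]});

      // clip by bisector of i and every other nearby seed k
      for (size_t qq = 0; qq < nbr[i].size() && !poly.empty(); ++qq) {
        int k = nbr[i][qq];
        if (k == j) continue;
        double wx = pts(k,0) - pts(i,0), wy = pts(k,1) - pts(i,1),
               wz = pts(k,2) - pts(i,2);
        // keep |x-pi|^2 <= |x-pk|^2  <=>  |pk|^2-|pi|^2 - 2 x.(pk-pi) >= 0
        double g0 = wx*(pts(k,0)+pts(i,0)) + wy*(pts(k,1)+pts(i,1)) +
                    wz*(pts(k,2)+pts(i,2)) -
                    2.0*(wx*mx + wy*my + wz*mz);
        double ga = -2.0*(wx*e1x + wy*e1y + wz*e1z);
        double gb = -2.0*(wx*e2x + wy*e2y + wz*e2z);
        // quick reject: does the bisector reach the disc at all?
        double gmax = g0 + rho * std::sqrt(ga*ga + gb*gb);
        if (gmax < 0) { poly.clear(); break; }
        double gmin = g0 - rho * std::sqrt(ga*ga + gb*gb);
        if (gmin >= 0) continue;  // disc untouched
        clipHalfPlane(poly, g0, ga, gb, scratch);
      }
      const double A = polyArea(poly);
      if (A > 1e-9) {
        ei.push_back(i + 1); ej.push_back(j + 1); earea.push_back(A);
        if (volumes) {
          const double h = 0.5 * d;
          vol[i] += h * A / 3.0;
          vol[j] += h * A / 3.0;
        }
      }
    }
  }

  if (volumes) {
    // spherical patch area by Fibonacci lattice
    const double golden = M_PI * (3.0 - std::sqrt(5.0));
    for (int i = 0; i < n; ++i) {
      int inside = 0;
      for (int t = 0; t < n_sphere; ++t) {
        double z = 1.0 - 2.0 * (t + 0.5) / n_sphere;
        double r = std::sqrt(std::max(0.0, 1.0 - z*z));
        double th = golden * t;
        double ux = r * std::cos(th), uy = r * std::sin(th), uz = z;
        double x = pts(i,0) + R*ux, y = pts(i,1) + R*uy, zz = pts(i,2) + R*uz;
        bool ok = true;
        for (size_t q = 0; q < nbr[i].size(); ++q) {
          int k = nbr[i][q];
          double dx = x - pts(k,0), dy = y - pts(k,1), dz = zz - pts(k,2);
          if (dx*dx + dy*dy + dz*dz < R2) { ok = false; break; }
        }
        if (ok) ++inside;
      }
      double Asph = 4.0 * M_PI * R2 * ((double)inside / n_sphere);
      vol[i] += R * Asph / 3.0;
    }
  }

  return List::create(
    _["i"] = wrap(ei), _["j"] = wrap(ej), _["area"] = wrap(earea),
    _["volume"] = volumes ? wrap(vol) : R_NilValue);
}
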