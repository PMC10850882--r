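#include <Rcpp.h>
using namespace Rcpp;

// Nearest-hit ray/triangle-mesh intersection (Moller-Trumbore), one ray per
// origin/direction row. Returns the hit distance, or -1 when the ray misses
// every triangle. Hits closer than `eps` are ignored so a ray starting on a
// surface does not hit it at distance zero.
// [[Rcpp::export(name = ".raycast_distance_cpp")]]
NumericVector raycast_distance_cpp(NumericMatrix origins, NumericMatrix dirs,
                                   NumericMatrix vertices, IntegerMatrix faces,
                                   double eps = 1e-6) {
  const int n_rays = origins.nrow();
  const int n_faces = faces.nrow();
  NumericVector out(n_rays, -1.0);

  std::vector<double> ax(n_faces), ay(n_faces), az(n_faces);
  std::vector<double> e1x(n_faces), e1y(n_faces), e1z(n_faces);
  std::vector<double> e2x(n_faces), e2y(n_faces), e2z(n_faces);
  for (int f = 0; f < n_faces; ++f) {
    int i0 = faces(f, 0) - 1, i1 = faces(f, 1) - 1, i2 = faces(f, 2) - 1;
    ax[f] = vertices(i0, 0); ay[f] = vertices(i0, 1); az[f] = vertices(i0, 2);
    e1x[f] = vertices(i1, 0) - ax[f];
    e1y[f] = vertices(i1, 1) - ay[f];
    e1z[f] = vertices(i1, 2) - az[f];
    e2x[f] = vertices(i2, 0) - ax[f];
    e2y[f] = vertices(i2, 1) - ay[f];
    e2z[f] = vertices(i2, 2) - az[f];
  }

  for (int r = 0; r < n_rays; ++r) {
    double ox = origins(r, 0), oy = origins(r, 1), oz = origins(r, 2);
    double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    double best = R_PosInf;
    for (int f = 0; f < n_faces; ++f) {
      // h = d x e2
      double hx = dy * e2z[f] - dz * e2y[f];
      double hy = dz * e2x[f] - dx * e2z[f];
      double hz = dx * e2y[f] - dy * e2x[f];
      double det = e1x[f] * hx + e1y[f] * hy + e1z[f] * hz;
      if (std::fabs(det) < 1e-12) continue;
      double inv = 1.0 / det;
      double sx = ox - ax[f], sy = oy - ay[f], sz = oz - az[f];
      double u = (sx * hx + sy * hy + sz * hz) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      // q = s x e1
      double qx = sy * e1z[f] - sz * e1y[f];
      double qy = sz * e1x[f] - sx * e1z[f];
      double qz = sx * e1y[f] - sy * e1x[f];
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double t = (e2x[f] * qx + e2y[f] * qy + e2z[f] * qz) * inv;
      if (t > eps && t < best) best = t;
    }
    if (R_finite(best)) out[r] = best;
  }
  return out;
}
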