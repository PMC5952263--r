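#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Even-odd point-in-polygon with an on-boundary tolerance: points within eps
// of any edge count as inside (closed-region rule).
// [[Rcpp::export]]
LogicalVector cpp_points_in_poly(NumericMatrix pts, NumericMatrix poly,
                                 double eps = 1e-9) {
  const int n = pts.nrow(), m = poly.nrow();
  LogicalVector out(n);
  for (int s = 0; s < n; ++s) {
    const double x = pts(s, 0), y = pts(s, 1);
    bool inside = false, boundary = false;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      const double xi = poly(i, 0), yi = poly(i, 1);
      const double xj = poly(j, 0), yj = poly(j, 1);
      // distance to segment
      const double dx = xj - xi, dy = yj - yi;
      const double L2 = dx * dx + dy * dy;
      double t = (L2 > 0.0) ? ((x - xi) * dx + (y - yi) * dy) / L2 : 0.0;
      if (t < 0.0) t = 0.0;
      if (t > 1.0) t = 1.0;
      const double px = xi + t * dx - x, py = yi + t * dy - y;
      if (px * px + py * py <= eps * eps) boundary = true;
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi)
        inside = !inside;
    }
    out[s] = inside || boundary;
  }
  return out;
}

// For each row of `from`, Euclidean distance to the nearest row of `to`.
// [[Rcpp::export]]
NumericVector cpp_nearest_dist(NumericMatrix from, NumericMatrix to) {
  const int n = from.nrow(), m = to.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double x = from(i, 0), y = from(i, 1);
    for (int j = 0; j < m; ++j) {
      const double dx = to(j, 0) - x, dy = to(j, 1) - y;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
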