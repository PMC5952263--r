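#include "transforms.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_apply_chain(NumericMatrix pts, List chain) {
  std::vector<Stage> stages = parse_chain(chain);
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  double p[3], q[3];
  for (int i = 0; i < n; ++i) {
    p[0] = pts(i, 0); p[1] = pts(i, 1); p[2] = pts(i, 2);
    for (size_t s = 0; s < stages.size(); ++s) {
      stages[s].apply(p, q);
      p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
    }
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
  }
  return out;
}

// Solve T(x) = y per row of pts by fixed-point iteration x <- x + (y - T(x)).
// Valid for chains whose displacement is a contraction (small smooth warps).
// [[Rcpp::export]]
List cpp_invert_chain(NumericMatrix pts, List chain, int max_iter, double tol) {
  std::vector<Stage> stages = parse_chain(chain);
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  NumericVector resid(n);
  double x[3], p[3], q[3];
  for (int i = 0; i < n; ++i) {
    const double y0 = pts(i, 0), y1 = pts(i, 1), y2 = pts(i, 2);
    x[0] = y0; x[1] = y1; x[2] = y2;
    double err = 0.0;
    for (int it = 0; it < max_iter; ++it) {
      p[0] = x[0]; p[1] = x[1]; p[2] = x[2];
      for (size_t s = 0; s < stages.size(); ++s) {
        stages[s].apply(p, q);
        p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
      }
      const double r0 = y0 - p[0], r1 = y1 - p[1], r2 = y2 - p[2];
      x[0] += r0; x[1] += r1; x[2] += r2;
      err = std::sqrt(r0 * r0 + r1 * r1 + r2 * r2);
      if (err < tol) break;
    }
    out(i, 0) = x[0]; out(i, 1) = x[1]; out(i, 2) = x[2];
    resid[i] = err;
  }
  return List::create(_["points"] = out, _["residual"] = resid);
}
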