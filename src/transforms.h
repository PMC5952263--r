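#pragma once
#include <Rcpp.h>
#include <cmath>
#include <vector>

// Cubic B-spline basis weights for fractional offset u in [0,1).
// w[l] multiplies the control point at index base + l, base = floor(t) - 1.
inline void bspline_w(double u, double *w) {
  const double u2 = u * u, u3 = u2 * u;
  w[0] = (1.0 - 3.0 * u + 3.0 * u2 - u3) / 6.0;
  w[1] = (4.0 - 6.0 * u2 + 3.0 * u3) / 6.0;
  w[2] = (1.0 + 3.0 * u + 3.0 * u2 - 3.0 * u3) / 6.0;
  w[3] = u3 / 6.0;
}

// d/du of the weights above (per-mm derivative needs division by spacing).
inline void bspline_dw(double u, double *w) {
  const double u2 = u * u;
  w[0] = (-3.0 + 6.0 * u - 3.0 * u2) / 6.0;
  w[1] = (-12.0 * u + 9.0 * u2) / 6.0;
  w[2] = (3.0 + 6.0 * u - 9.0 * u2) / 6.0;
  w[3] = 3.0 * u2 / 6.0;
}

// Value of the (centred) cubic B-spline kernel beta3 at x, support (-2, 2).
inline double beta3(double x) {
  const double a = std::fabs(x);
  if (a >= 2.0) return 0.0;
  if (a >= 1.0) { const double t = 2.0 - a; return t * t * t / 6.0; }
  return (4.0 - 6.0 * a * a + 3.0 * a * a * a) / 6.0;
}

inline double beta3_deriv(double x) {
  const double a = std::fabs(x), s = (x < 0.0) ? -1.0 : 1.0;
  if (a >= 2.0) return 0.0;
  if (a >= 1.0) { const double t = 2.0 - a; return -s * t * t / 2.0; }
  return s * (-2.0 * a + 1.5 * a * a);
}

struct BSplineGrid {
  double org[3], sp[3];
  int dim[3];
  const double *coef;  // length dim0*dim1*dim2*3, R column-major

  inline double cval(int i, int j, int k, int d) const {
    if (i < 0 || j < 0 || k < 0 || i >= dim[0] || j >= dim[1] || k >= dim[2])
      return 0.0;  // identity displacement beyond the control lattice
    return coef[i + (size_t)dim[0] * (j + (size_t)dim[1] * (k + (size_t)dim[2] * d))];
  }

  // Displacement at point p; optionally record the 64 supporting weights.
  inline void disp(const double *p, double *d,
                   int *base = nullptr, double *wxyz = nullptr) const {
    double wx[4], wy[4], wz[4];
    int b[3];
    const double *wlist[3] = {wx, wy, wz};
    for (int ax = 0; ax < 3; ++ax) {
      const double t = (p[ax] - org[ax]) / sp[ax];
      const double fl = std::floor(t);
      b[ax] = (int)fl - 1;
      bspline_w(t - fl, const_cast<double *>(wlist[ax]));
    }
    d[0] = d[1] = d[2] = 0.0;
    for (int n = 0; n < 4; ++n)
      for (int m = 0; m < 4; ++m) {
        const double wym = wy[m] * wz[n];
        for (int l = 0; l < 4; ++l) {
          const double w = wx[l] * wym;
          for (int dd = 0; dd < 3; ++dd)
            d[dd] += w * cval(b[0] + l, b[1] + m, b[2] + n, dd);
        }
      }
    if (base) { base[0] = b[0]; base[1] = b[1]; base[2] = b[2]; }
    if (wxyz) {
      for (int l = 0; l < 4; ++l) {
        wxyz[l] = wx[l]; wxyz[4 + l] = wy[l]; wxyz[8 + l] = wz[l];
      }
    }
  }
};

// One component transform of a chain, parsed from its R list form.
struct Stage {
  int kind;  // 0 = translation/couch_shift, 1 = rigid, 2 = affine, 3 = bspline
  double t[3], R[9], c[3];
  BSplineGrid grid;
  Rcpp::NumericVector keep;  // keeps bspline coefficients alive

  void apply(const double *p, double *q) const {
    switch (kind) {
    case 0:
      q[0] = p[0] + t[0]; q[1] = p[1] + t[1]; q[2] = p[2] + t[2];
      break;
    case 1:
    case 2: {
      const double v0 = p[0] - c[0], v1 = p[1] - c[1], v2 = p[2] - c[2];
      q[0] = R[0] * v0 + R[3] * v1 + R[6] * v2 + c[0] + t[0];
      q[1] = R[1] * v0 + R[4] * v1 + R[7] * v2 + c[1] + t[1];
      q[2] = R[2] * v0 + R[5] * v1 + R[8] * v2 + c[2] + t[2];
      break;
    }
    default: {
      double d[3];
      grid.disp(p, d);
      q[0] = p[0] + d[0]; q[1] = p[1] + d[1]; q[2] = p[2] + d[2];
    }
    }
  }
};

inline void euler_to_matrix(double ax, double ay, double az, double *R) {
  // R = Rz(az) %*% Ry(ay) %*% Rx(ax), column-major 3x3
  const double cx = std::cos(ax), sx = std::sin(ax);
  const double cy = std::cos(ay), sy = std::sin(ay);
  const double cz = std::cos(az), sz = std::sin(az);
  R[0] = cz * cy;               R[1] = sz * cy;               R[2] = -sy;
  R[3] = cz * sy * sx - sz * cx; R[4] = sz * sy * sx + cz * cx; R[5] = cy * sx;
  R[6] = cz * sy * cx + sz * sx; R[7] = sz * sy * cx - cz * sx; R[8] = cy * cx;
}

inline Stage parse_stage(const Rcpp::List &st) {
  Stage s;
  const std::string kind = Rcpp::as<std::string>(st["kind"]);
  Rcpp::NumericVector par = st["params"];
  for (int i = 0; i < 9; ++i) s.R[i] = 0.0;
  s.R[0] = s.R[4] = s.R[8] = 1.0;
  s.t[0] = s.t[1] = s.t[2] = 0.0;
  s.c[0] = s.c[1] = s.c[2] = 0.0;
  if (kind == "translation" || kind == "couch_shift") {
    s.kind = 0;
    for (int i = 0; i < 3; ++i) s.t[i] = par[i];
  } else if (kind == "rigid") {
    s.kind = 1;
    euler_to_matrix(par[0], par[1], par[2], s.R);
    for (int i = 0; i < 3; ++i) s.t[i] = par[3 + i];
    Rcpp::NumericVector cc = st["center"];
    for (int i = 0; i < 3; ++i) s.c[i] = cc[i];
  } else if (kind == "affine") {
    s.kind = 2;
    for (int i = 0; i < 9; ++i) s.R[i] = par[i];  // column-major A
    for (int i = 0; i < 3; ++i) s.t[i] = par[9 + i];
    Rcpp::NumericVector cc = st["center"];
    for (int i = 0; i < 3; ++i) s.c[i] = cc[i];
  } else if (kind == "bspline") {
    s.kind = 3;
    Rcpp::NumericVector org = st["grid_origin"], sp = st["grid_spacing"];
    Rcpp::IntegerVector dm = st["grid_dim"];
    s.keep = par;
    for (int i = 0; i < 3; ++i) {
      s.grid.org[i] = org[i];
      s.grid.sp[i] = sp[i];
      s.grid.dim[i] = dm[i];
    }
    s.grid.coef = s.keep.begin();
  } else {
    Rcpp::stop("unknown transform kind '%s'", kind.c_str());
  }
  return s;
}

inline std::vector<Stage> parse_chain(const Rcpp::List &chain) {
  std::vector<Stage> out;
  for (R_xlen_t i = 0; i < chain.size(); ++i)
    out.push_back(parse_stage(Rcpp::as<Rcpp::List>(chain[i])));
  return out;
}
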