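#include "transforms.h"
using namespace Rcpp;

static inline size_t vidx(int i, int j, int k, const int *d) {
  return (size_t)i + (size_t)d[0] * ((size_t)j + (size_t)d[1] * (size_t)k);
}

// Trilinear interpolation of a volume at mm points. Points outside the box
// spanned by the first and last voxel centres are flagged not inside and get
// NA. Optionally returns the spatial gradient of the interpolant (per mm).
// [[Rcpp::export]]
List cpp_trilinear(NumericVector vol, IntegerVector dim, NumericVector sp,
                   NumericVector org, NumericMatrix pts, bool grad = false) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const int n = pts.nrow();
  NumericVector val(n);
  LogicalVector inside(n);
  NumericMatrix gmat = grad ? NumericMatrix(n, 3) : NumericMatrix(0, 0);
  const double *v = vol.begin();
  const double eps = 1e-9;

  for (int s = 0; s < n; ++s) {
    double t[3];
    bool ok = true;
    for (int ax = 0; ax < 3; ++ax) {
      t[ax] = (pts(s, ax) - org[ax]) / sp[ax];
      if (!(t[ax] >= -eps && t[ax] <= d[ax] - 1 + eps)) ok = false;
    }
    inside[s] = ok;
    if (!ok) {
      val[s] = NA_REAL;
      if (grad) { gmat(s, 0) = gmat(s, 1) = gmat(s, 2) = 0.0; }
      continue;
    }
    int i0[3];
    double u[3];
    for (int ax = 0; ax < 3; ++ax) {
      int c = (int)std::floor(t[ax]);
      if (c < 0) c = 0;
      if (c > d[ax] - 2) c = d[ax] - 2;
      if (d[ax] == 1) c = 0;
      i0[ax] = c;
      u[ax] = t[ax] - c;
      if (d[ax] == 1) u[ax] = 0.0;
    }
    const int i1 = (d[0] == 1) ? i0[0] : i0[0] + 1;
    const int j1 = (d[1] == 1) ? i0[1] : i0[1] + 1;
    const int k1 = (d[2] == 1) ? i0[2] : i0[2] + 1;
    const double c000 = v[vidx(i0[0], i0[1], i0[2], d)];
    const double c100 = v[vidx(i1, i0[1], i0[2], d)];
    const double c010 = v[vidx(i0[0], j1, i0[2], d)];
    const double c110 = v[vidx(i1, j1, i0[2], d)];
    const double c001 = v[vidx(i0[0], i0[1], k1, d)];
    const double c101 = v[vidx(i1, i0[1], k1, d)];
    const double c011 = v[vidx(i0[0], j1, k1, d)];
    const double c111 = v[vidx(i1, j1, k1, d)];
    const double ux = u[0], uy = u[1], uz = u[2];
    const double c00 = c000 * (1 - ux) + c100 * ux;
    const double c10 = c010 * (1 - ux) + c110 * ux;
    const double c01 = c001 * (1 - ux) + c101 * ux;
    const double c11 = c011 * (1 - ux) + c111 * ux;
    const double c0 = c00 * (1 - uy) + c10 * uy;
    const double c1 = c01 * (1 - uy) + c11 * uy;
    val[s] = c0 * (1 - uz) + c1 * uz;
    if (grad) {
      const double dx0 = (c100 - c000) * (1 - uy) + (c110 - c010) * uy;
      const double dx1 = (c101 - c001) * (1 - uy) + (c111 - c011) * uy;
      gmat(s, 0) = (dx0 * (1 - uz) + dx1 * uz) / sp[0];
      const double dy0 = (c10 - c00), dy1 = (c11 - c01);
      gmat(s, 1) = (dy0 * (1 - uz) + dy1 * uz) / sp[1];
      gmat(s, 2) = (c1 - c0) / sp[2];
    }
  }
  if (grad)
    return List::create(_["values"] = val, _["inside"] = inside, _["grad"] = gmat);
  return List::create(_["values"] = val, _["inside"] = inside);
}

// Separable Gaussian smoothing, replicate boundary; sigma in voxels per axis.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const size_t ntot = (size_t)d[0] * d[1] * d[2];
  std::vector<double> a(vol.begin(), vol.end()), b(ntot);
  for (int ax = 0; ax < 3; ++ax) {
    const double sg = sigma[ax];
    if (sg <= 0.0) continue;
    const int rad = (int)std::ceil(3.0 * sg);
    std::vector<double> ker(2 * rad + 1);
    double ksum = 0.0;
    for (int i = -rad; i <= rad; ++i) {
      ker[i + rad] = std::exp(-0.5 * i * i / (sg * sg));
      ksum += ker[i + rad];
    }
    for (auto &k : ker) k /= ksum;
    const int nax = d[ax];
    // iterate over all lines along axis ax
    const int dims[3] = {d[0], d[1], d[2]};
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    for (int j2 = 0; j2 < dims[o2]; ++j2)
      for (int j1 = 0; j1 < dims[o1]; ++j1) {
        for (int i = 0; i < nax; ++i) {
          double acc = 0.0;
          for (int kk = -rad; kk <= rad; ++kk) {
            int ii = i + kk;
            if (ii < 0) ii = 0;
            if (ii > nax - 1) ii = nax - 1;
            int idx3[3];
            idx3[ax] = ii; idx3[o1] = j1; idx3[o2] = j2;
            acc += ker[kk + rad] * a[vidx(idx3[0], idx3[1], idx3[2], d)];
          }
          int idx3[3];
          idx3[ax] = i; idx3[o1] = j1; idx3[o2] = j2;
          b[vidx(idx3[0], idx3[1], idx3[2], d)] = acc;
        }
      }
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}

// Block-average down-sampling by integer factors per axis (trailing partial
// blocks are dropped). Used for archival-style image down-sampling.
// [[Rcpp::export]]
List cpp_block_average(NumericVector vol, IntegerVector dim, IntegerVector factor) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const int f[3] = {factor[0], factor[1], factor[2]};
  const int nd[3] = {d[0] / f[0], d[1] / f[1], d[2] / f[2]};
  NumericVector out((size_t)nd[0] * nd[1] * nd[2]);
  const double *v = vol.begin();
  const double inv = 1.0 / (f[0] * f[1] * f[2]);
  for (int k = 0; k < nd[2]; ++k)
    for (int j = 0; j < nd[1]; ++j)
      for (int i = 0; i < nd[0]; ++i) {
        double acc = 0.0;
        for (int kk = 0; kk < f[2]; ++kk)
          for (int jj = 0; jj < f[1]; ++jj)
            for (int ii = 0; ii < f[0]; ++ii)
              acc += v[vidx(i * f[0] + ii, j * f[1] + jj, k * f[2] + kk, d)];
        out[vidx(i, j, k, nd)] = acc * inv;
      }
  out.attr("newdim") = IntegerVector::create(nd[0], nd[1], nd[2]);
  return List::create(_["values"] = out,
                      _["dim"] = IntegerVector::create(nd[0], nd[1], nd[2]));
}
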