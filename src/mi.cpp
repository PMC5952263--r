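#include "transforms.h"
using namespace Rcpp;

// Minimal trilinear sampler shared by the metric code (value + gradient).
struct VolumeRef {
  const double *v;
  int d[3];
  double sp[3], org[3];

  bool sample(const double *p, double &val, double *g) const {
    double t[3];
    const double eps = 1e-9;
    for (int ax = 0; ax < 3; ++ax) {
      t[ax] = (p[ax] - org[ax]) / sp[ax];
      if (!(t[ax] >= -eps && t[ax] <= d[ax] - 1 + eps)) return false;
    }
    int i0[3];
    double u[3];
    for (int ax = 0; ax < 3; ++ax) {
      int c = (int)std::floor(t[ax]);
      if (c < 0) c = 0;
      if (c > d[ax] - 2) c = d[ax] - 2;
      if (d[ax] == 1) c = 0;
      i0[ax] = c;
      u[ax] = (d[ax] == 1) ? 0.0 : t[ax] - c;
    }
    auto at = [&](int i, int j, int k) {
      return v[(size_t)i + (size_t)d[0] * ((size_t)j + (size_t)d[1] * (size_t)k)];
    };
    const int i1 = (d[0] == 1) ? i0[0] : i0[0] + 1;
    const int j1 = (d[1] == 1) ? i0[1] : i0[1] + 1;
    const int k1 = (d[2] == 1) ? i0[2] : i0[2] + 1;
    const double c000 = at(i0[0], i0[1], i0[2]), c100 = at(i1, i0[1], i0[2]);
    const double c010 = at(i0[0], j1, i0[2]), c110 = at(i1, j1, i0[2]);
    const double c001 = at(i0[0], i0[1], k1), c101 = at(i1, i0[1], k1);
    const double c011 = at(i0[0], j1, k1), c111 = at(i1, j1, k1);
    const double ux = u[0], uy = u[1], uz = u[2];
    const double c00 = c000 * (1 - ux) + c100 * ux;
    const double c10 = c010 * (1 - ux) + c110 * ux;
    const double c01 = c001 * (1 - ux) + c101 * ux;
    const double c11 = c011 * (1 - ux) + c111 * ux;
    const double c0 = c00 * (1 - uy) + c10 * uy;
    const double c1 = c01 * (1 - uy) + c11 * uy;
    val = c0 * (1 - uz) + c1 * uz;
    if (g) {
      const double dx0 = (c100 - c000) * (1 - uy) + (c110 - c010) * uy;
      const double dx1 = (c101 - c001) * (1 - uy) + (c111 - c011) * uy;
      g[0] = (dx0 * (1 - uz) + dx1 * uz) / sp[0];
      g[1] = ((c10 - c00) * (1 - uz) + (c11 - c01) * uz) / sp[1];
      g[2] = (c1 - c0) / sp[2];
    }
    return true;
  }
};

static VolumeRef make_volref(const NumericVector &vol, const IntegerVector &dim,
                             const NumericVector &sp, const NumericVector &org) {
  VolumeRef r;
  r.v = vol.begin();
  for (int i = 0; i < 3; ++i) {
    r.d[i] = dim[i];
    r.sp[i] = sp[i];
    r.org[i] = org[i];
  }
  return r;
}

static double mi_from_hist(const std::vector<double> &p, int nfb, int nmb,
                           double n) {
  std::vector<double> pf(nfb, 0.0), pm(nmb, 0.0);
  for (int f = 0; f < nfb; ++f)
    for (int m = 0; m < nmb; ++m) {
      pf[f] += p[f + (size_t)nfb * m];
      pm[m] += p[f + (size_t)nfb * m];
    }
  double mi = 0.0;
  for (int f = 0; f < nfb; ++f)
    for (int m = 0; m < nmb; ++m) {
      const double pj = p[f + (size_t)nfb * m];
      if (pj > 0.0) mi += pj * std::log(pj / (pf[f] * pm[m]));
    }
  (void)n;
  return mi;
}

// Mutual information of paired samples after mapping fixed-frame points
// through a transform chain. fbin holds 0-based fixed-intensity bins
// (negative = excluded). Moving intensities are binned on
// [mmin, mmin + nmb*mwidth]; parzen = TRUE spreads each moving sample over
// four bins with a cubic B-spline window (smooth in the parameters),
// parzen = FALSE uses hard binning (classic joint-histogram MI).
// [[Rcpp::export]]
List cpp_chain_mi(NumericMatrix pts, IntegerVector fbin, List chain,
                  NumericVector vol, IntegerVector dim, NumericVector sp,
                  NumericVector org, double mmin, double mwidth, int nfb,
                  int nmb, bool parzen) {
  std::vector<Stage> stages = parse_chain(chain);
  VolumeRef mov = make_volref(vol, dim, sp, org);
  const int n = pts.nrow();
  std::vector<double> hist((size_t)nfb * nmb, 0.0);
  int used = 0, attempted = 0;
  double p[3], q[3];
  for (int s = 0; s < n; ++s) {
    if (fbin[s] < 0) continue;
    ++attempted;
    p[0] = pts(s, 0); p[1] = pts(s, 1); p[2] = pts(s, 2);
    for (size_t st = 0; st < stages.size(); ++st) {
      stages[st].apply(p, q);
      p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
    }
    double val;
    if (!mov.sample(p, val, nullptr)) continue;
    ++used;
    if (parzen) {
      const double m = (val - mmin) / mwidth - 0.5;
      const int k0 = (int)std::floor(m) - 1;
      for (int k = k0; k <= k0 + 3; ++k) {
        int kc = k;
        if (kc < 0) kc = 0;
        if (kc > nmb - 1) kc = nmb - 1;
        hist[(size_t)fbin[s] + (size_t)nfb * kc] += beta3(m - k);
      }
    } else {
      int mb = (int)std::floor((val - mmin) / mwidth);
      if (mb < 0) mb = 0;
      if (mb > nmb - 1) mb = nmb - 1;
      hist[(size_t)fbin[s] + (size_t)nfb * mb] += 1.0;
    }
  }
  double mi = NA_REAL;
  if (used > 0) {
    for (auto &h : hist) h /= used;
    mi = mi_from_hist(hist, nfb, nmb, used);
  }
  return List::create(_["mi"] = mi, _["n_used"] = used,
                      _["n_attempted"] = attempted);
}

// Parzen-window MI and its analytic gradient with respect to the B-spline
// control-point coefficients of the final stage. pts are the sample points
// already mapped through all preceding (frozen) stages.
// [[Rcpp::export]]
List cpp_bspline_mi_grad(NumericMatrix pts, IntegerVector fbin, List stage,
                         NumericVector vol, IntegerVector dim, NumericVector sp,
                         NumericVector org, double mmin, double mwidth, int nfb,
                         int nmb) {
  Stage bst = parse_stage(stage);
  if (bst.kind != 3) stop("final stage must be a bspline transform");
  VolumeRef mov = make_volref(vol, dim, sp, org);
  const int n = pts.nrow();

  std::vector<double> hist((size_t)nfb * nmb, 0.0);
  std::vector<double> mcont(n), grads((size_t)n * 3), wstore((size_t)n * 12);
  std::vector<int> bstore((size_t)n * 3);
  std::vector<char> ok(n, 0);
  int used = 0, attempted = 0;

  for (int s = 0; s < n; ++s) {
    if (fbin[s] < 0) continue;
    ++attempted;
    double y[3] = {pts(s, 0), pts(s, 1), pts(s, 2)};
    double d3[3];
    int base[3];
    double w12[12];
    bst.grid.disp(y, d3, base, w12);
    const double z[3] = {y[0] + d3[0], y[1] + d3[1], y[2] + d3[2]};
    double val, g3[3];
    if (!mov.sample(z, val, g3)) continue;
    ok[s] = 1;
    ++used;
    const double m = (val - mmin) / mwidth - 0.5;
    mcont[s] = m;
    for (int i = 0; i < 3; ++i) {
      grads[(size_t)s * 3 + i] = g3[i];
      bstore[(size_t)s * 3 + i] = base[i];
    }
    for (int i = 0; i < 12; ++i) wstore[(size_t)s * 12 + i] = w12[i];
    const int k0 = (int)std::floor(m) - 1;
    for (int k = k0; k <= k0 + 3; ++k) {
      int kc = k;
      if (kc < 0) kc = 0;
      if (kc > nmb - 1) kc = nmb - 1;
      hist[(size_t)fbin[s] + (size_t)nfb * kc] += beta3(m - k);
    }
  }

  const size_t ncoef =
      (size_t)bst.grid.dim[0] * bst.grid.dim[1] * bst.grid.dim[2] * 3;
  NumericVector grad(ncoef);
  if (used == 0)
    return List::create(_["mi"] = NA_REAL, _["grad"] = grad, _["n_used"] = 0,
                        _["n_attempted"] = attempted);

  for (auto &h : hist) h /= used;
  std::vector<double> pm(nmb, 0.0);
  for (int f = 0; f < nfb; ++f)
    for (int m = 0; m < nmb; ++m) pm[m] += hist[f + (size_t)nfb * m];
  const double mi = mi_from_hist(hist, nfb, nmb, used);

  const int gd0 = bst.grid.dim[0], gd1 = bst.grid.dim[1], gd2 = bst.grid.dim[2];
  const double tiny = 1e-12;
  for (int s = 0; s < n; ++s) {
    if (!ok[s]) continue;
    const double m = mcont[s];
    const int f = fbin[s];
    double dmidm = 0.0;
    const int k0 = (int)std::floor(m) - 1;
    for (int k = k0; k <= k0 + 3; ++k) {
      int kc = k;
      if (kc < 0) kc = 0;
      if (kc > nmb - 1) kc = nmb - 1;
      const double pj = hist[(size_t)f + (size_t)nfb * kc];
      if (pj > tiny && pm[kc] > tiny)
        dmidm += beta3_deriv(m - k) * std::log(pj / pm[kc]);
    }
    dmidm /= used;
    const double a = dmidm / mwidth;
    const double gv[3] = {a * grads[(size_t)s * 3],
                          a * grads[(size_t)s * 3 + 1],
                          a * grads[(size_t)s * 3 + 2]};
    const double *wx = &wstore[(size_t)s * 12];
    const double *wy = wx + 4, *wz = wx + 8;
    const int *b = &bstore[(size_t)s * 3];
    for (int nn = 0; nn < 4; ++nn) {
      const int ck = b[2] + nn;
      if (ck < 0 || ck >= gd2) continue;
      for (int mm = 0; mm < 4; ++mm) {
        const int cj = b[1] + mm;
        if (cj < 0 || cj >= gd1) continue;
        const double wyz = wy[mm] * wz[nn];
        for (int ll = 0; ll < 4; ++ll) {
          const int ci = b[0] + ll;
          if (ci < 0 || ci >= gd0) continue;
          const double w = wx[ll] * wyz;
          for (int dd = 0; dd < 3; ++dd)
            grad[(size_t)ci +
                 (size_t)gd0 * ((size_t)cj +
                                (size_t)gd1 * ((size_t)ck + (size_t)gd2 * dd))] +=
                w * gv[dd];
        }
      }
    }
  }
  return List::create(_["mi"] = mi, _["grad"] = grad, _["n_used"] = used,
                      _["n_attempted"] = attempted);
}
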