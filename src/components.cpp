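#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 3D logical array (6- or 26-connectivity).
// Returns integer labels, 0 = background, components numbered from 1 in
// first-encounter (lowest linear index) order.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity = 26) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offi, offj, offk;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        offi.push_back(di); offj.push_back(dj); offk.push_back(dk);
      }
  int next = 0;
  std::vector<size_t> stack;
  for (size_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (size_t t = 0; t < offi.size(); ++t) {
        const int ii = i + offi[t], jj = j + offj[t], kk = k + offk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        const size_t q = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
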