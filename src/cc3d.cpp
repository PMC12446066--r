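#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of a 3D foreground mask.
// `mask` is a logical vector in R array order (first dimension fastest),
// `dims` its (n1, n2, n3) extents, `connectivity` one of 6, 18, 26.
// Returns an integer vector of the same length: 0 background, components
// labeled 1..K in order of first (linear-index) occurrence.
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets in (d1,d2,d3)
  std::vector<int> d1s, d2s, d3s;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        d1s.push_back(a); d2s.push_back(b); d3s.push_back(c);
      }
  const int ndir = (int)d1s.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i1 = (int)(cur % n1);
      int i2 = (int)((cur / n1) % n2);
      int i3 = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int k = 0; k < ndir; ++k) {
        int j1 = i1 + d1s[k], j2 = i2 + d2s[k], j3 = i3 + d3s[k];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
        R_xlen_t j = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
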