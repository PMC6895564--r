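#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Connected-component labeling of a binary raster.
// Labels are assigned in row-major order of each component's first pixel,
// so the output is deterministic for a given mask and connectivity.
// [[Rcpp::export]]
IntegerMatrix label_cc_int(const IntegerMatrix& mask, const int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  stack.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      // column-major storage, but the scan order only fixes label numbering;
      // relabeling to row-major first-pixel order happens below
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        ++next;
        lab(r, c) = next;
        stack.push_back(std::make_pair(r, c));
        while (!stack.empty()) {
          std::pair<int, int> p = stack.back();
          stack.pop_back();
          for (int k = 0; k < nn; ++k) {
            const int rr = p.first + dr8[k], cc = p.second + dc8[k];
            if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
                mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  // relabel so that component ids follow the row-major position of each
  // component's first pixel (contract: deterministic row-major ordering)
  std::vector<long long> first(next + 1, -1);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      const int l = lab(r, c);
      if (l > 0 && first[l] < 0) first[l] = (long long)r * nc + c;
    }
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i + 1;
  std::sort(order.begin(), order.end(),
            [&first](int a, int b) { return first[a] < first[b]; });
  std::vector<int> newid(next + 1, 0);
  for (int i = 0; i < next; ++i) newid[order[i]] = i + 1;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = newid[lab(r, c)];
  return lab;
}
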