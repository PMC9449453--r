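// Connected-component labeling (8-connectivity) for binary masks.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.push_back(r0 + H * c0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int r = p % H, c = p / H;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + H * cc);
            }
          }
      }
    }
  return lab;
}
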