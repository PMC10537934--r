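#include <Rcpp.h>
using namespace Rcpp;

// Largest axis-aligned all-true rectangle in a binary mask, by the
// row-stacked histogram method (O(rows * cols)). Every maximum-area
// rectangle is non-extendable and therefore appears among the per-row
// histogram candidates, so scanning all candidates with the tie-break
// (smallest top row, then smallest left column, then largest height)
// is exact over the full set of maximum-area rectangles.
// [[Rcpp::export(name = ".largest_rect_cpp")]]
IntegerVector largest_rect_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> heights(nc, 0);
  std::vector<int> stack_idx(nc + 1);
  // best rectangle: 1-based top, left, height, width
  long best_area = 0;
  int b_top = 0, b_left = 0, b_h = 0, b_w = 0;

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c)
      heights[c] = mask(r, c) ? heights[c] + 1 : 0;

    // monotone stack over the histogram, sentinel bar of height 0 at nc
    int top = -1;
    for (int c = 0; c <= nc; ++c) {
      int h = (c < nc) ? heights[c] : 0;
      // pop on >= so the stack stays strictly increasing; the last bar of
      // an equal-height run yields the full-span candidate
      while (top >= 0 && heights[stack_idx[top]] >= h) {
        int idx = stack_idx[top--];
        int hh = heights[idx];
        int left = (top >= 0) ? stack_idx[top] + 1 : 0;
        int ww = c - left;
        long area = (long)hh * ww;
        int cand_top = r - hh + 2;   // 1-based
        int cand_left = left + 1;    // 1-based
        bool better = false;
        if (area > best_area) better = true;
        else if (area == best_area && area > 0) {
          if (cand_top < b_top) better = true;
          else if (cand_top == b_top) {
            if (cand_left < b_left) better = true;
            else if (cand_left == b_left && hh > b_h) better = true;
          }
        }
        if (better) {
          best_area = area; b_top = cand_top; b_left = cand_left;
          b_h = hh; b_w = ww;
        }
      }
      stack_idx[++top] = c;
    }
  }
  return IntegerVector::create(_["top_row"] = b_top, _["left_col"] = b_left,
                               _["height"] = b_h, _["width"] = b_w);
}
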