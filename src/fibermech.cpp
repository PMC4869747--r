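#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static double median_of(std::vector<double>& v) {
  const size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.begin() + n / 2);
  return 0.5 * (hi + v[n / 2 - 1]);
}

// Masked median filter: per-pixel median of `img` over a window x window
// neighbourhood (clipped at the borders, no padding), using only pixels where
// `mask` is FALSE.  Windows with fewer than `min_px` usable pixels are grown
// by `grow_step` pixels per side until enough are available or the window
// spans the whole image; a window that still has none falls back to the
// global unmasked median.
// [[Rcpp::export]]
NumericMatrix masked_median_cpp(NumericMatrix img, LogicalMatrix mask,
                                int window, int grow_step, int min_px) {
  const int nr = img.nrow(), nc = img.ncol();
  if (window > nr || window > nc)
    stop("filtering window is larger than the image");
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)window * window * 4);

  // global fallback
  std::vector<double> allv;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (!mask(i, j)) allv.push_back(img(i, j));
  double global_med;
  if (allv.empty()) {
    allv.assign(img.begin(), img.end());
  }
  global_med = median_of(allv);

  const int half0 = window / 2;
  const int half_max = std::max(nr, nc); // covers whole image

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int half = half0;
      double med = global_med;
      while (true) {
        buf.clear();
        const int r0 = std::max(0, i - half), r1 = std::min(nr - 1, i + half);
        const int c0 = std::max(0, j - half), c1 = std::min(nc - 1, j + half);
        for (int c = c0; c <= c1; ++c)
          for (int r = r0; r <= r1; ++r)
            if (!mask(r, c)) buf.push_back(img(r, c));
        if ((int)buf.size() >= min_px || half >= half_max) {
          if (!buf.empty()) med = median_of(buf);
          break;
        }
        half += grow_step;
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Orientation-consistency trim.  A fiber pixel is kept iff the mean of
// cos(axial difference) between its orientation and those of all other
// fiber pixels in a (window x window) neighbourhood exceeds `threshold`.
// The axial difference folds the 0/180-degree seam (1 and 179 degrees are
// 2 degrees apart); differences up to `slack` radians (the angular
// resolution of the kernel bank) are treated as perfect alignment.
// Pixels with fewer than `min_neighbors` fiber neighbours are removed:
// orientation agreement among a handful of pixels is weak evidence of a
// fiber (a fiber running through the window contributes on the order of
// window * band-width neighbours), and tiny isolated coherent groups are
// exactly the bright-spot remnants the refinement exists to remove.
// [[Rcpp::export]]
LogicalMatrix orientation_trim_cpp(LogicalMatrix mask, NumericMatrix theta,
                                   int window, double threshold,
                                   double slack, int min_neighbors) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int half = window / 2;
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) { out(i, j) = FALSE; continue; }
      const double tp = theta(i, j);
      double s = 0.0; int n = 0;
      const int r0 = std::max(0, i - half), r1 = std::min(nr - 1, i + half);
      const int c0 = std::max(0, j - half), c1 = std::min(nc - 1, j + half);
      for (int c = c0; c <= c1; ++c) {
        for (int r = r0; r <= r1; ++r) {
          if ((r == i && c == j) || !mask(r, c)) continue;
          // orientations lie in [0, pi), so |tp - tn| < pi already
          double d = std::fabs(tp - theta(r, c));
          if (d > M_PI / 2) d = M_PI - d;   // axial fold
          d = std::max(0.0, d - slack);
          s += std::cos(d);
          ++n;
        }
      }
      out(i, j) = (n >= std::max(min_neighbors, 1)) &&
        (s / n > threshold);
    }
  }
  return out;
}
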