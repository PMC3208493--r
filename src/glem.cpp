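#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Core GLEM accumulation. For every mask-true pixel the first-order entropy
// of the mask-true pixels inside its w x w window (clipped at the image
// border) is computed, binned onto B equal-width bins over [0, entropy_max],
// and the (grey level, entropy bin) count matrix is accumulated. Only
// mask-true pixels enter the window histograms: background glass would
// otherwise dominate windows near the nuclear rim.
//
// Pixels must already be re-quantised to [0, G-1]; the R wrapper validates.
// [[Rcpp::export]]
List glem_core(const IntegerMatrix& pixels, const LogicalMatrix& mask,
               int window, int G, int B, double entropy_max) {
  const int nr = pixels.nrow(), nc = pixels.ncol();
  const int half = window / 2;
  NumericMatrix P(G, B);
  NumericMatrix emap(nr, nc);
  std::fill(emap.begin(), emap.end(), NA_REAL);
  std::vector<int> hist(G, 0);
  std::vector<int> touched;
  touched.reserve((size_t)window * window);
  const double inv_log2 = 1.0 / std::log(2.0);
  double total = 0.0;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      const int g = pixels(r, c);
      if (g < 0 || g >= G)
        stop("pixel value outside [0, G-1] at a mask-true position");
      touched.clear();
      int counted = 0;
      const int r0 = std::max(0, r - half), r1 = std::min(nr - 1, r + half);
      const int c0 = std::max(0, c - half), c1 = std::min(nc - 1, c + half);
      for (int cc = c0; cc <= c1; ++cc) {
        for (int rr = r0; rr <= r1; ++rr) {
          if (!mask(rr, cc)) continue;
          const int v = pixels(rr, cc);
          if (hist[v]++ == 0) touched.push_back(v);
          ++counted;
        }
      }
      double H = 0.0;
      for (size_t k = 0; k < touched.size(); ++k) {
        const double p = (double)hist[touched[k]] / counted;
        H -= p * std::log(p) * inv_log2;
        hist[touched[k]] = 0;
      }
      if (H < 0.0) H = 0.0;  // guard against -0 rounding
      int j = (int)std::floor(H * B / entropy_max);
      if (j >= B) j = B - 1;
      emap(r, c) = H;
      P(g, j) += 1.0;
      total += 1.0;
    }
  }
  if (total > 0) {
    for (R_xlen_t k = 0; k < P.size(); ++k) P[k] /= total;
  }
  return List::create(_["P"] = P, _["entropy_map"] = emap,
                      _["n_pixels_counted"] = total);
}
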