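#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median filter with a disk-shaped structuring element (pixels at Euclidean
// distance <= radius from the centre). Borders use symmetric (reflect)
// padding, i.e. index -1 maps to 0, n maps to n-1.
// [[Rcpp::export]]
NumericMatrix disk_median_cpp(NumericMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dr, dc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) {
        dr.push_back(a);
        dc.push_back(b);
      }
  const int K = (int) dr.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(K);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int k = 0; k < K; ++k) {
        int r = i + dr[k];
        int c = j + dc[k];
        if (r < 0) r = -r - 1;
        if (r >= nr) r = 2 * nr - 1 - r;
        if (c < 0) c = -c - 1;
        if (c >= nc) c = 2 * nc - 1 - c;
        buf[k] = img(r, c);
      }
      std::nth_element(buf.begin(), buf.begin() + K / 2, buf.end());
      double med = buf[K / 2];
      if (K % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + K / 2 - 1,
                         buf.begin() + K / 2);
        med = 0.5 * (med + buf[K / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}
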