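#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Symmetric reflection: index i in [-inf, 2n) mapped into [0, n).
// Edge pixel is repeated (…, x1, x0 | x0, x1, …), matching the documented
// border rule for both rank and averaging filters.
static inline int reflect(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  if (i < 0) i = 0;          // guard for very small n
  if (i >= n) i = n - 1;
  return i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int size) {
  if (size < 1 || size % 2 == 0) stop("window size must be odd and positive");
  int h = img.nrow(), w = img.ncol(), r = size / 2;
  NumericMatrix out(h, w);
  std::vector<double> buf(size * size);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int k = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = reflect(j + dj, w);
        for (int di = -r; di <= r; ++di) {
          buf[k++] = img(reflect(i + di, h), jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix mean_filter_cpp(NumericMatrix img, int size) {
  if (size < 1 || size % 2 == 0) stop("window size must be odd and positive");
  int h = img.nrow(), w = img.ncol(), r = size / 2;
  NumericMatrix out(h, w);
  double norm = 1.0 / (size * size);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double s = 0.0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = reflect(j + dj, w);
        for (int di = -r; di <= r; ++di) {
          s += img(reflect(i + di, h), jj);
        }
      }
      out(i, j) = s * norm;
    }
  }
  return out;
}
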