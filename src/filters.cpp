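#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median filter on a replicate-padded image. `padded` must have
// (rows + win - 1) x (cols + win - 1) entries; returns rows x cols.
// [[Rcpp::export(name = ".medianFilterCpp")]]
NumericMatrix medianFilterCpp(NumericMatrix padded, int rows, int cols,
                              int win) {
  NumericMatrix out(rows, cols);
  const int n = win * win;
  std::vector<double> buf(n);
  for (int j = 0; j < cols; ++j) {
    for (int i = 0; i < rows; ++i) {
      int k = 0;
      for (int dj = 0; dj < win; ++dj)
        for (int di = 0; di < win; ++di)
          buf[k++] = padded(i + di, j + dj);
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      out(i, j) = buf[n / 2];
    }
  }
  return out;
}
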