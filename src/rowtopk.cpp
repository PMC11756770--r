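#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// k largest absolute values per row of Z, sorted descending.
// Row r of the result holds |Z|_(D) >= ... >= |Z|_(D-k+1), i.e. the
// absolute Z scores whose two-sided p-values are the k smallest.
// [[Rcpp::export(name = ".row_abs_topk")]]
NumericMatrix row_abs_topk(NumericMatrix Z, int k) {
  const int B = Z.nrow(), D = Z.ncol();
  if (k < 1 || k > D) stop("k out of range");
  NumericMatrix out(B, k);
  std::vector<double> buf(D);
  for (int r = 0; r < B; ++r) {
    for (int j = 0; j < D; ++j) buf[j] = std::fabs(Z(r, j));
    std::nth_element(buf.begin(), buf.begin() + k - 1, buf.end(),
                     std::greater<double>());
    std::sort(buf.begin(), buf.begin() + k, std::greater<double>());
    for (int j = 0; j < k; ++j) out(r, j) = buf[j];
  }
  return out;
}

// Full ascending row sort (used for Simes over all D p-values).
// [[Rcpp::export(name = ".row_sort_asc")]]
NumericMatrix row_sort_asc(NumericMatrix X) {
  const int B = X.nrow(), D = X.ncol();
  NumericMatrix out(B, D);
  std::vector<double> buf(D);
  for (int r = 0; r < B; ++r) {
    for (int j = 0; j < D; ++j) buf[j] = X(r, j);
    std::sort(buf.begin(), buf.end());
    for (int j = 0; j < D; ++j) out(r, j) = buf[j];
  }
  return out;
}
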