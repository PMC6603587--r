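#include <Rcpp.h>
using namespace Rcpp;

// Gather the im2col matrix for a batch. X is n x F (one sample per
// row, flat feature index = (c-1)*H*W + (y-1)*W + x). idx holds, for
// each output position p (1..hw) and kernel entry q (1..cin9), the
// 1-based source feature index, 0 for a padded tap; it is ordered
// j = (p-1)*cin9 + q. The result B is (n*hw) x cin9 with row
// i + (p-1)*n, ready for B %*% W.
// [[Rcpp::export]]
NumericMatrix im2col_gather(const NumericMatrix& X, const IntegerVector& idx,
                            int hw) {
  const int n = X.nrow();
  const int cin9 = idx.size() / hw;
  NumericMatrix B(n * hw, cin9);
  for (int q = 0; q < cin9; ++q) {
    double* out = &B(0, q);
    for (int p = 0; p < hw; ++p) {
      int src = idx[p * cin9 + q];
      if (src == 0) continue;             // padded tap: stays zero
      const double* in = &X(0, src - 1);
      double* o = out + p * n;
      for (int i = 0; i < n; ++i) o[i] = in[i];
    }
  }
  return B;
}

// Scatter-add the im2col gradient back onto the input feature map:
// inverse of im2col_gather. dcols is (n*hw) x cin9.
// [[Rcpp::export]]
NumericMatrix col2im_scatter(const NumericMatrix& dcols,
                             const IntegerVector& idx, int n, int f_in) {
  const int hw = dcols.nrow() / n;
  const int cin9 = dcols.ncol();
  NumericMatrix dX(n, f_in);
  for (int q = 0; q < cin9; ++q) {
    const double* col = &dcols(0, q);
    for (int p = 0; p < hw; ++p) {
      int dst = idx[p * cin9 + q];
      if (dst == 0) continue;
      double* o = &dX(0, dst - 1);
      const double* in = col + p * n;
      for (int i = 0; i < n; ++i) o[i] += in[i];
    }
  }
  return dX;
}
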