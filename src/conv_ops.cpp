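#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are R arrays dim c(H, W, C), column-major.
// im2col unrolls k x k patches so a convolution becomes one gemm:
//   Y (Cout x P) = W (Cout x k*k*Cin) %*% cols (k*k*Cin x P)
// Row order within a column: kh fastest, then kw, then channel, matching
// the weight layout produced by conv_init() on the R side.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int P  = Ho * Wo;
  const int K  = k * k * C;
  NumericMatrix out(K, P);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = wo * Ho + ho;            // column index
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      double* col = op + (size_t)p * K;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          const bool win = (wi >= 0 && wi < W);
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            double v = 0.0;
            if (win && hi >= 0 && hi < H) v = xc[(size_t)wi * H + hi];
            col[c * k * k + kw * k + kh] = v;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add patch columns back into an H x W x C array.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int K  = k * k * C;
  NumericVector x((size_t)H * W * C);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = wo * Ho + ho;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      const double* col = cp + (size_t)p * K;
      for (int c = 0; c < C; ++c) {
        double* xc = xp + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            xc[(size_t)wi * H + hi] += col[c * k * k + kw * k + kh];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}
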