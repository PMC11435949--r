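#include <Rcpp.h>
using namespace Rcpp;

// im2col for 2-D convolution on (C, H, W, B) column-major tensors.
// Rows of the output are ordered c fastest, then kernel tap (i fast, j slow);
// columns are (ho fast, wo, b). Zero padding is implicit via bounds checks.
// [[Rcpp::export]]
NumericMatrix cpp_im2col2d(NumericVector x, int C, int H, int W, int B,
                           int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Hout = (H + 2 * ph - kh) / sh + 1;
  const int Wout = (W + 2 * pw - kw) / sw + 1;
  const int ncol = Hout * Wout * B;
  NumericMatrix cols(C * kh * kw, ncol);
  const double *px = x.begin();
  double *pc = cols.begin();
  const int nrow = C * kh * kw;
  for (int b = 0; b < B; ++b) {
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        const R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * b);
        double *dst = pc + col * nrow;
        for (int j = 0; j < kw; ++j) {
          const int w = wo * sw + j - pw;
          for (int i = 0; i < kh; ++i) {
            const int h = ho * sh + i - ph;
            double *d = dst + ((R_xlen_t)j * kh + i) * C;
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) d[c] = 0.0;
            } else {
              const double *s = px + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * b));
              for (int c = 0; c < C; ++c) d[c] = s[c];
            }
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add adjoint of cpp_im2col2d
// [[Rcpp::export]]
NumericVector cpp_col2im2d(NumericMatrix dcols, int C, int H, int W, int B,
                           int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Hout = (H + 2 * ph - kh) / sh + 1;
  const int Wout = (W + 2 * pw - kw) / sw + 1;
  NumericVector dx((R_xlen_t)C * H * W * B);
  const double *pc = dcols.begin();
  double *px = dx.begin();
  const int nrow = C * kh * kw;
  for (int b = 0; b < B; ++b) {
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        const R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * b);
        const double *src = pc + col * nrow;
        for (int j = 0; j < kw; ++j) {
          const int w = wo * sw + j - pw;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int h = ho * sh + i - ph;
            if (h < 0 || h >= H) continue;
            const double *s = src + ((R_xlen_t)j * kh + i) * C;
            double *d = px + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * b));
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  return dx;
}

// im2col for causal dilated 1-D convolution on (C, T, B): left pad (k-1)*dil
// [[Rcpp::export]]
NumericMatrix cpp_im2col1d(NumericVector x, int C, int T, int B,
                           int k, int dil) {
  const int pl = (k - 1) * dil;
  NumericMatrix cols(C * k, (R_xlen_t)T * B);
  const double *px = x.begin();
  double *pc = cols.begin();
  const int nrow = C * k;
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      const R_xlen_t col = (R_xlen_t)t + (R_xlen_t)T * b;
      double *dst = pc + col * nrow;
      for (int i = 0; i < k; ++i) {
        const int tt = t + i * dil - pl;
        double *d = dst + (R_xlen_t)i * C;
        if (tt < 0) {
          for (int c = 0; c < C; ++c) d[c] = 0.0;
        } else {
          const double *s = px + (R_xlen_t)C * (tt + (R_xlen_t)T * b);
          for (int c = 0; c < C; ++c) d[c] = s[c];
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im1d(NumericMatrix dcols, int C, int T, int B,
                           int k, int dil) {
  const int pl = (k - 1) * dil;
  NumericVector dx((R_xlen_t)C * T * B);
  const double *pc = dcols.begin();
  double *px = dx.begin();
  const int nrow = C * k;
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      const R_xlen_t col = (R_xlen_t)t + (R_xlen_t)T * b;
      const double *src = pc + col * nrow;
      for (int i = 0; i < k; ++i) {
        const int tt = t + i * dil - pl;
        if (tt < 0) continue;
        const double *s = src + (R_xlen_t)i * C;
        double *d = px + (R_xlen_t)C * (tt + (R_xlen_t)T * b);
        for (int c = 0; c < C; ++c) d[c] += s[c];
      }
    }
  }
  return dx;
}
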