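#include <Rcpp.h>
using namespace Rcpp;

// Patch-extraction (im2col) and its adjoint (col2im) for strided 2-D
// convolution.  Activation layout is column-major (C, H, W, B): channel
// fastest, then row, column, batch.  The column matrix has one column per
// output location (oy fastest, then ox, then b) and C*kh*kw rows indexed
// (c, ky, kx) with c fastest.  Out-of-range taps read as zero (im2col) or
// are dropped (col2im), which implements zero padding of pt rows on top
// and pl columns on the left (bottom/right padding is implicit in OH/OW).

// [[Rcpp::export]]
NumericMatrix cd_im2col(NumericVector x, int C, int H, int W, int B,
                        int kh, int kw, int stride, int pt, int pl,
                        int OH, int OW) {
  const int R = C * kh * kw;
  NumericMatrix col(R, (R_xlen_t)OH * OW * B);
  const double* xp = REAL(x);
  double* cp = REAL(col);
  for (int b = 0; b < B; ++b) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        R_xlen_t cbase = ((R_xlen_t)oy + (R_xlen_t)OH * (ox + (R_xlen_t)OW * b)) * R;
        for (int kx = 0; kx < kw; ++kx) {
          int ix = ox * stride - pl + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            int iy = oy * stride - pt + ky;
            if (iy < 0 || iy >= H) continue;
            R_xlen_t ro = cbase + (R_xlen_t)C * (ky + kh * kx);
            R_xlen_t xi = (R_xlen_t)C * (iy + (R_xlen_t)H * (ix + (R_xlen_t)W * b));
            for (int c = 0; c < C; ++c) cp[ro + c] = xp[xi + c];
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cd_col2im(NumericMatrix col, int C, int H, int W, int B,
                        int kh, int kw, int stride, int pt, int pl,
                        int OH, int OW) {
  const int R = C * kh * kw;
  NumericVector x((R_xlen_t)C * H * W * B);
  double* xp = REAL(x);
  const double* cp = REAL(col);
  for (int b = 0; b < B; ++b) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        R_xlen_t cbase = ((R_xlen_t)oy + (R_xlen_t)OH * (ox + (R_xlen_t)OW * b)) * R;
        for (int kx = 0; kx < kw; ++kx) {
          int ix = ox * stride - pl + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            int iy = oy * stride - pt + ky;
            if (iy < 0 || iy >= H) continue;
            R_xlen_t ro = cbase + (R_xlen_t)C * (ky + kh * kx);
            R_xlen_t xi = (R_xlen_t)C * (iy + (R_xlen_t)H * (ix + (R_xlen_t)W * b));
            for (int c = 0; c < C; ++c) xp[xi + c] += cp[ro + c];
          }
        }
      }
    }
  }
  return x;
}
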