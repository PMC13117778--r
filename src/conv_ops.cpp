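// Lowering of 2-D convolution to GEMM: im2col gather and its adjoint
// col2im scatter-add over H x W x N x C arrays (spatial, batch, channel).
// Rows of the column matrix are output positions (oi, oj, n), columns are
// kernel taps (u, v, c) with u fastest.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_taps(NumericVector xp, IntegerVector dims, int kh,
                          int kw, int stride, int oh, int ow) {
  const int Hp = dims[0], Wp = dims[1], N = dims[2], C = dims[3];
  const R_xlen_t P = (R_xlen_t)oh * ow * N;
  const int K = kh * kw * C;
  NumericMatrix out(P, K);
  const double* px = xp.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int v = 0; v < kw; ++v)
      for (int u = 0; u < kh; ++u) {
        const int r = u + v * kh + c * kh * kw;
        double* col = po + (R_xlen_t)r * P;
        R_xlen_t q = 0;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t base_nc = ((R_xlen_t)c * N + n) * Hp * Wp;
          for (int oj = 0; oj < ow; ++oj) {
            const R_xlen_t base =
              base_nc + (R_xlen_t)(v + oj * stride) * Hp + u;
            for (int oi = 0; oi < oh; ++oi)
              col[q++] = px[base + (R_xlen_t)oi * stride];
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_taps(NumericMatrix dxcol, IntegerVector dims, int kh,
                          int kw, int stride, int oh, int ow) {
  const int Hp = dims[0], Wp = dims[1], N = dims[2], C = dims[3];
  const R_xlen_t P = (R_xlen_t)oh * ow * N;
  NumericVector dxp((R_xlen_t)Hp * Wp * N * C);
  double* pd = dxp.begin();
  const double* pc = dxcol.begin();
  for (int c = 0; c < C; ++c)
    for (int v = 0; v < kw; ++v)
      for (int u = 0; u < kh; ++u) {
        const int r = u + v * kh + c * kh * kw;
        const double* col = pc + (R_xlen_t)r * P;
        R_xlen_t q = 0;
        for (int n = 0; n < N; ++n) {
          const R_xlen_t base_nc = ((R_xlen_t)c * N + n) * Hp * Wp;
          for (int oj = 0; oj < ow; ++oj) {
            const R_xlen_t base =
              base_nc + (R_xlen_t)(v + oj * stride) * Hp + u;
            for (int oi = 0; oi < oh; ++oi)
              pd[base + (R_xlen_t)oi * stride] += col[q++];
          }
        }
      }
  return dxp;
}
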