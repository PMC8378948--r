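#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D valid-padding convolution over a batch of volumes.
//
// x: [N, X, Y, Z, Ci]  (N = batch * time frames; column-major, N fastest)
// w: [kx, ky, kz, Ci, Co]
// b: [Co]
// Output: [N, Xo, Yo, Zo, Co] with Xo = floor((X - kx)/s) + 1, etc.
//
// The batch axis is innermost in memory, so the hot loops run contiguously
// over N. For each output position all Co channels are accumulated in an
// L1-resident buffer so every input patch is read once, not Co times.

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int N = xd[0], X = xd[1], Y = xd[2], Z = xd[3], Ci = xd[4];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Co = wd[4];
  const int Xo = (X - kx) / stride + 1;
  const int Yo = (Y - ky) / stride + 1;
  const int Zo = (Z - kz) / stride + 1;

  NumericVector out((R_xlen_t)N * Xo * Yo * Zo * Co);
  out.attr("dim") = IntegerVector::create(N, Xo, Yo, Zo, Co);
  double *po = out.begin();
  const double *px = x.begin(), *pw = w.begin();
  const R_xlen_t ostride = (R_xlen_t)N * Xo * Yo * Zo;

  std::vector<double> acc((size_t)Co * N);

  for (int zo = 0; zo < Zo; ++zo)
    for (int yo = 0; yo < Yo; ++yo)
      for (int xo = 0; xo < Xo; ++xo) {
        for (int co = 0; co < Co; ++co)
          std::fill(acc.begin() + (size_t)co * N,
                    acc.begin() + (size_t)(co + 1) * N, b[co]);
        const int xi0 = xo * stride, yi0 = yo * stride, zi0 = zo * stride;
        for (int ci = 0; ci < Ci; ++ci)
          for (int dz = 0; dz < kz; ++dz)
            for (int dy = 0; dy < ky; ++dy)
              for (int dx = 0; dx < kx; ++dx) {
                const double *in = px + (R_xlen_t)N *
                  ((xi0 + dx) + (R_xlen_t)X * ((yi0 + dy) + (R_xlen_t)Y * ((zi0 + dz) + (R_xlen_t)Z * ci)));
                const double *wk = pw + kx * ((R_xlen_t)dy + ky * (dz + (R_xlen_t)kz * ci)) + dx;
                for (int co = 0; co < Co; ++co) {
                  const double wv = wk[(R_xlen_t)kx * ky * kz * Ci * co];
                  double *a = acc.data() + (size_t)co * N;
                  for (int n = 0; n < N; ++n) a[n] += wv * in[n];
                }
              }
        double *obase = po + (R_xlen_t)N * (xo + (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo));
        for (int co = 0; co < Co; ++co) {
          double *o = obase + ostride * co;
          const double *a = acc.data() + (size_t)co * N;
          for (int n = 0; n < N; ++n) o[n] = a[n];
        }
      }
  return out;
}

// Gradients of the valid 3D convolution: given upstream gy on the output,
// returns dL/dx, dL/dw, dL/db in one pass over output positions, with the
// Co upstream-gradient rows buffered per position.

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int N = xd[0], X = xd[1], Y = xd[2], Z = xd[3], Ci = xd[4];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Co = wd[4];
  const int Xo = gd[1], Yo = gd[2], Zo = gd[3];
  const R_xlen_t wchan = (R_xlen_t)kx * ky * kz * Ci;

  NumericVector gx((R_xlen_t)N * X * Y * Z * Ci);
  gx.attr("dim") = xd;
  NumericVector gw(wchan * Co);
  gw.attr("dim") = wd;
  NumericVector gb(Co);

  double *pgx = gx.begin(), *pgw = gw.begin();
  const double *px = x.begin(), *pw = w.begin(), *pgy = gy.begin();
  const R_xlen_t ostride = (R_xlen_t)N * Xo * Yo * Zo;

  std::vector<double> gbuf((size_t)Co * N);

  for (int zo = 0; zo < Zo; ++zo)
    for (int yo = 0; yo < Yo; ++yo)
      for (int xo = 0; xo < Xo; ++xo) {
        const double *gbase = pgy + (R_xlen_t)N * (xo + (R_xlen_t)Xo * (yo + (R_xlen_t)Yo * zo));
        for (int co = 0; co < Co; ++co) {
          const double *g = gbase + ostride * co;
          double *gb_row = gbuf.data() + (size_t)co * N;
          double s = 0.0;
          for (int n = 0; n < N; ++n) {
            gb_row[n] = g[n];
            s += g[n];
          }
          gb[co] += s;
        }
        const int xi0 = xo * stride, yi0 = yo * stride, zi0 = zo * stride;
        for (int ci = 0; ci < Ci; ++ci)
          for (int dz = 0; dz < kz; ++dz)
            for (int dy = 0; dy < ky; ++dy)
              for (int dx = 0; dx < kx; ++dx) {
                const R_xlen_t off = (R_xlen_t)N *
                  ((xi0 + dx) + (R_xlen_t)X * ((yi0 + dy) + (R_xlen_t)Y * ((zi0 + dz) + (R_xlen_t)Z * ci)));
                const double *in = px + off;
                double *gi = pgx + off;
                const R_xlen_t wi0 = dx + kx * ((R_xlen_t)dy + ky * (dz + (R_xlen_t)kz * ci));
                for (int co = 0; co < Co; ++co) {
                  const double wv = pw[wi0 + wchan * co];
                  const double *g = gbuf.data() + (size_t)co * N;
                  double accw = 0.0;
                  for (int n = 0; n < N; ++n) {
                    accw += in[n] * g[n];
                    gi[n] += wv * g[n];
                  }
                  pgw[wi0 + wchan * co] += accw;
                }
              }
      }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
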