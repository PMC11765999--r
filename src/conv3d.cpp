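#include <Rcpp.h>
using namespace Rcpp;

// Layout convention: a volume is a numeric vector in column-major order with
// dims (H, W, D, C). Patches are unrolled in the same order, so a column block
// of the patch matrix corresponds to one input channel.

static inline int out_len(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export(name = ".vol2col")]]
NumericMatrix vol2col(NumericVector x, IntegerVector dims, IntegerVector ksize,
                      IntegerVector stride, IntegerVector pad) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int kh = ksize[0], kw = ksize[1], kd = ksize[2];
  const int sh = stride[0], sw = stride[1], sd = stride[2];
  const int ph = pad[0], pw = pad[1], pd = pad[2];
  const int oh = out_len(H, kh, sh, ph);
  const int ow = out_len(W, kw, sw, pw);
  const int od = out_len(D, kd, sd, pd);
  const int npos = oh * ow * od;
  const int plen = kh * kw * kd * C;
  NumericMatrix cols(npos, plen);
  const double *xp = x.begin();
  double *cp = cols.begin();

  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (R_xlen_t)c * H * W * D;
    for (int dz = 0; dz < kd; ++dz) {
      for (int dx = 0; dx < kw; ++dx) {
        for (int dy = 0; dy < kh; ++dy) {
          const int col = c * kh * kw * kd + dz * kh * kw + dx * kh + dy;
          double *dst = cp + (R_xlen_t)col * npos;
          int pos = 0;
          for (int z = 0; z < od; ++z) {
            const int iz = z * sd - pd + dz;
            const bool zok = iz >= 0 && iz < D;
            for (int xw = 0; xw < ow; ++xw) {
              const int ix = xw * sw - pw + dx;
              const bool xok = ix >= 0 && ix < W;
              for (int y = 0; y < oh; ++y, ++pos) {
                const int iy = y * sh - ph + dy;
                if (zok && xok && iy >= 0 && iy < H)
                  dst[pos] = xc[(R_xlen_t)iz * H * W + (R_xlen_t)ix * H + iy];
                else
                  dst[pos] = 0.0;
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of vol2col: scatter-add patch columns back into a volume.
// [[Rcpp::export(name = ".col2vol")]]
NumericVector col2vol(NumericMatrix cols, IntegerVector dims, IntegerVector ksize,
                      IntegerVector stride, IntegerVector pad) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int kh = ksize[0], kw = ksize[1], kd = ksize[2];
  const int sh = stride[0], sw = stride[1], sd = stride[2];
  const int ph = pad[0], pw = pad[1], pd = pad[2];
  const int oh = out_len(H, kh, sh, ph);
  const int ow = out_len(W, kw, sw, pw);
  const int od = out_len(D, kd, sd, pd);
  const int npos = oh * ow * od;
  NumericVector x((R_xlen_t)H * W * D * C);
  const double *cp = cols.begin();
  double *xp = x.begin();

  for (int c = 0; c < C; ++c) {
    double *xc = xp + (R_xlen_t)c * H * W * D;
    for (int dz = 0; dz < kd; ++dz) {
      for (int dx = 0; dx < kw; ++dx) {
        for (int dy = 0; dy < kh; ++dy) {
          const int col = c * kh * kw * kd + dz * kh * kw + dx * kh + dy;
          const double *src = cp + (R_xlen_t)col * npos;
          int pos = 0;
          for (int z = 0; z < od; ++z) {
            const int iz = z * sd - pd + dz;
            const bool zok = iz >= 0 && iz < D;
            for (int xw = 0; xw < ow; ++xw) {
              const int ix = xw * sw - pw + dx;
              const bool xok = ix >= 0 && ix < W;
              for (int y = 0; y < oh; ++y, ++pos) {
                const int iy = y * sh - ph + dy;
                if (zok && xok && iy >= 0 && iy < H)
                  xc[(R_xlen_t)iz * H * W + (R_xlen_t)ix * H + iy] += src[pos];
              }
            }
          }
        }
      }
    }
  }
  return x;
}
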