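// Low-level raster kernels: im2col/col2im convolution support, affine
// bilinear warping, bicubic resampling and joint histograms.
// Arrays are R column-major; image stacks are laid out (H, W, C, N).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Unfold a (H,W,C,N) stack into a ((N*Ho*Wo) x (k*k*C)) matrix so that a
// convolution becomes a single GEMM. Row index = ho + Ho*wo + Ho*Wo*n,
// column index = dh + k*dw + k*k*c. Zero padding outside the image.
// [[Rcpp::export]]
NumericMatrix im2col_c(NumericVector x, int H, int W, int C, int N,
                       int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded image");
  const R_xlen_t nrow = (R_xlen_t)N * Ho * Wo;
  NumericMatrix out(nrow, (R_xlen_t)k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const R_xlen_t col = dh + (R_xlen_t)k * dw + (R_xlen_t)k * k * c;
        double* ocol = op + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xim = xp + (R_xlen_t)H * W * c + (R_xlen_t)H * W * C * n;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + dw;
            double* orun = ocol + (R_xlen_t)Ho * wo + (R_xlen_t)Ho * Wo * n;
            if (w < 0 || w >= W) {
              for (int ho = 0; ho < Ho; ++ho) orun[ho] = 0.0;
              continue;
            }
            const double* xcol = xim + (R_xlen_t)H * w;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + dh;
              orun[ho] = (h < 0 || h >= H) ? 0.0 : xcol[h];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_c: scatter-add columns back into a (H,W,C,N) stack.
// [[Rcpp::export]]
NumericVector col2im_c(NumericMatrix cols, int H, int W, int C, int N,
                       int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)H * W * C * N);
  const R_xlen_t nrow = (R_xlen_t)N * Ho * Wo;
  if (cols.nrow() != nrow || cols.ncol() != (R_xlen_t)k * k * C)
    stop("column matrix does not match the stated geometry");
  const double* cp = cols.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const R_xlen_t col = dh + (R_xlen_t)k * dw + (R_xlen_t)k * k * c;
        const double* ccol = cp + col * nrow;
        for (int n = 0; n < N; ++n) {
          double* xim = op + (R_xlen_t)H * W * c + (R_xlen_t)H * W * C * n;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + dw;
            if (w < 0 || w >= W) continue;
            const double* crun = ccol + (R_xlen_t)Ho * wo + (R_xlen_t)Ho * Wo * n;
            double* xcol = xim + (R_xlen_t)H * w;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + dh;
              if (h >= 0 && h < H) xcol[h] += crun[ho];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// Inverse-warp with bilinear sampling. A is a 2x3 matrix mapping OUTPUT
// (row, col) 0-based coordinates to INPUT coordinates:
//   src_r = A(0,0)*r + A(0,1)*c + A(0,2)
//   src_c = A(1,0)*r + A(1,1)*c + A(1,2)
// Pixels sampling outside the input get `fill` (may be NA).
// [[Rcpp::export]]
NumericVector warp_affine_c(NumericVector img, int H, int W, int C,
                            NumericMatrix A, int outH, int outW, double fill) {
  NumericVector out((R_xlen_t)outH * outW * C);
  const double* ip = img.begin();
  double* op = out.begin();
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  for (int c = 0; c < outW; ++c) {
    for (int r = 0; r < outH; ++r) {
      const double sr = a00 * r + a01 * c + a02;
      const double sc = a10 * r + a11 * c + a12;
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      const R_xlen_t oidx = r + (R_xlen_t)outH * c;
      if (r0 < 0 || c0 < 0 || r0 + 1 > H - 1 + 1 || c0 + 1 > W - 1 + 1 ||
          sr < 0.0 || sc < 0.0 || sr > H - 1.0 || sc > W - 1.0) {
        for (int ch = 0; ch < C; ++ch)
          op[oidx + (R_xlen_t)outH * outW * ch] = fill;
        continue;
      }
      const int r1 = (r0 == H - 1) ? r0 : r0 + 1;
      const int c1 = (c0 == W - 1) ? c0 : c0 + 1;
      const double fr = sr - r0, fc = sc - c0;
      for (int ch = 0; ch < C; ++ch) {
        const double* im = ip + (R_xlen_t)H * W * ch;
        const double v00 = im[r0 + (R_xlen_t)H * c0];
        const double v10 = im[r1 + (R_xlen_t)H * c0];
        const double v01 = im[r0 + (R_xlen_t)H * c1];
        const double v11 = im[r1 + (R_xlen_t)H * c1];
        op[oidx + (R_xlen_t)outH * outW * ch] =
          (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
          (1 - fr) * fc * v01 + fr * fc * v11;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(outH, outW, C);
  return out;
}

static inline double cubic_keys(double t) {
  // Keys bicubic kernel, a = -0.5 (the convention of MATLAB imresize).
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
  if (t < 2.0)  return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
  return 0.0;
}

// Bicubic resampling with pixel-centre alignment:
// src = (dst + 0.5) * (in/out) - 0.5, edge samples clamped.
// [[Rcpp::export]]
NumericVector resize_bicubic_c(NumericVector img, int H, int W, int C,
                               int outH, int outW) {
  NumericVector out((R_xlen_t)outH * outW * C);
  const double* ip = img.begin();
  double* op = out.begin();
  const double fy = (double)H / outH, fx = (double)W / outW;
  std::vector<double> wy(4), wx(4);
  for (int c = 0; c < outW; ++c) {
    const double sx = (c + 0.5) * fx - 0.5;
    const int x0 = (int)std::floor(sx) - 1;
    for (int i = 0; i < 4; ++i) wx[i] = cubic_keys(sx - (x0 + i));
    for (int r = 0; r < outH; ++r) {
      const double sy = (r + 0.5) * fy - 0.5;
      const int y0 = (int)std::floor(sy) - 1;
      for (int i = 0; i < 4; ++i) wy[i] = cubic_keys(sy - (y0 + i));
      for (int ch = 0; ch < C; ++ch) {
        const double* im = ip + (R_xlen_t)H * W * ch;
        double acc = 0.0;
        for (int j = 0; j < 4; ++j) {
          int xx = x0 + j;
          xx = xx < 0 ? 0 : (xx >= W ? W - 1 : xx);
          double rowacc = 0.0;
          for (int i = 0; i < 4; ++i) {
            int yy = y0 + i;
            yy = yy < 0 ? 0 : (yy >= H ? H - 1 : yy);
            rowacc += wy[i] * im[yy + (R_xlen_t)H * xx];
          }
          acc += wx[j] * rowacc;
        }
        op[r + (R_xlen_t)outH * c + (R_xlen_t)outH * outW * ch] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(outH, outW, C);
  return out;
}

// Joint histogram of two equal-length vectors with values binned on [0,1].
// Pairs where either value is NA/NaN are skipped (warp fill regions).
// [[Rcpp::export]]
NumericMatrix joint_hist_c(NumericVector x, NumericVector y, int bins) {
  if (x.size() != y.size()) stop("joint histogram inputs differ in length");
  NumericMatrix h(bins, bins);
  const double* xp = x.begin();
  const double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double xv = xp[i], yv = yp[i];
    if (ISNAN(xv) || ISNAN(yv)) continue;
    int bx = (int)(xv * bins);
    int by = (int)(yv * bins);
    bx = bx < 0 ? 0 : (bx >= bins ? bins - 1 : bx);
    by = by < 0 ? 0 : (by >= bins ? bins - 1 : by);
    h(bx, by) += 1.0;
  }
  return h;
}
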