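// Minimal convolution primitives for the dual-encoder networks.
// Tensors are R arrays in column-major (H, W, C, B) layout; kernels are
// (kh, kw, Cin, Cout) with kh = kw = 3, stride 1, zero padding 1, so that
// flattening the first three kernel dims matches the im2col column order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3(const double* x, int H, int W, int C) {
  arma::mat M(H * W, 9 * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        int col = (ky + 1) + 3 * (kx + 1) + 9 * ci;
        double* m = M.colptr(col);
        for (int w = 0; w < W; ++w) {
          int sw = w + kx;
          if (sw < 0 || sw >= W) continue;
          int h0 = std::max(0, -ky), h1 = std::min(H, H - ky);
          const double* src = xc + (size_t)sw * H + ky;
          double* dst = m + (size_t)w * H;
          for (int h = h0; h < h1; ++h) dst[h] = src[h];
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Cout = wd[3];
  if (wd[0] != 3 || wd[1] != 3 || wd[2] != C)
    stop("kernel must be 3x3xCinxCout matching input channels");
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(bias.begin()), Cout, false, true);
  NumericVector out((R_xlen_t)(H * W * Cout * B));
  out.attr("dim") = IntegerVector::create(H, W, Cout, B);
  for (int b = 0; b < B; ++b) {
    arma::mat M = im2col3(x.begin() + (size_t)b * H * W * C, H, W, C);
    arma::mat Y = M * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), out.begin() + (size_t)b * H * W * Cout);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Cout = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, Cout, false, true);
  NumericVector dx((R_xlen_t)(H * W * C * B));
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)(9 * C * Cout));
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), 9 * C, Cout, false, true);
  NumericVector db(Cout);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  for (int b = 0; b < B; ++b) {
    arma::mat M = im2col3(x.begin() + (size_t)b * H * W * C, H, W, C);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)b * H * W * Cout,
                 H * W, Cout, false, true);
    dWm += M.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dM = dY * Wm.t();
    // col2im scatter-add
    double* dxb = dx.begin() + (size_t)b * H * W * C;
    for (int ci = 0; ci < C; ++ci) {
      double* dxc = dxb + (size_t)ci * H * W;
      for (int kx = -1; kx <= 1; ++kx) {
        for (int ky = -1; ky <= 1; ++ky) {
          int col = (ky + 1) + 3 * (kx + 1) + 9 * ci;
          const double* m = dM.colptr(col);
          for (int w2 = 0; w2 < W; ++w2) {
            int sw = w2 + kx;
            if (sw < 0 || sw >= W) continue;
            int h0 = std::max(0, -ky), h1 = std::min(H, H - ky);
            double* dst = dxc + (size_t)sw * H + ky;
            const double* src = m + (size_t)w2 * H;
            for (int h = h0; h < h1; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  if (H % 2 || W % 2) stop("avgpool2 requires even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)((size_t)Ho * Wo * C * B));
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* op = out.begin();
  size_t ncb = (size_t)C * B;
  for (size_t cb = 0; cb < ncb; ++cb) {
    const double* xs = xp + cb * H * W;
    double* os = op + cb * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        os[h + (size_t)w * Ho] = 0.25 *
          (xs[2 * h + (size_t)(2 * w) * H] + xs[2 * h + 1 + (size_t)(2 * w) * H] +
           xs[2 * h + (size_t)(2 * w + 1) * H] + xs[2 * h + 1 + (size_t)(2 * w + 1) * H]);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_backward(NumericVector dy, IntegerVector in_dim) {
  int H = in_dim[0], W = in_dim[1], C = in_dim[2], B = in_dim[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)((size_t)H * W * C * B));
  dx.attr("dim") = in_dim;
  const double* dp = dy.begin();
  double* xp = dx.begin();
  size_t ncb = (size_t)C * B;
  for (size_t cb = 0; cb < ncb; ++cb) {
    const double* ds = dp + cb * Ho * Wo;
    double* xs = xp + cb * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double g = 0.25 * ds[h + (size_t)w * Ho];
        xs[2 * h + (size_t)(2 * w) * H] += g;
        xs[2 * h + 1 + (size_t)(2 * w) * H] += g;
        xs[2 * h + (size_t)(2 * w + 1) * H] += g;
        xs[2 * h + 1 + (size_t)(2 * w + 1) * H] += g;
      }
  }
  return dx;
}

// Bilinear rotation about the image center with mirror-reflection padding.
// Exact at multiples of 90 degrees on square images.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_reflect(NumericMatrix img, double angle_deg) {
  int n = img.nrow(), m = img.ncol();
  double a = angle_deg - 360.0 * std::floor(angle_deg / 360.0);
  if (a == 0.0) return img;
  double th = -a * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cr = (n + 1) / 2.0, cc = (m + 1) / 2.0;
  NumericMatrix out(n, m);
  auto reflect = [](double x, int k) -> int {
    if (k == 1) return 0;
    double period = 2.0 * (k - 1);
    double p = (x - 1.0) - period * std::floor((x - 1.0) / period);
    double r = std::min(p, period - p);
    return (int)(r + 0.5);
  };
  for (int j = 0; j < m; ++j) {
    double dc = (j + 1) - cc;
    for (int i = 0; i < n; ++i) {
      double dr = (i + 1) - cr;
      double sr = ct * dr - st * dc + cr;
      double sc = st * dr + ct * dc + cc;
      double r0 = std::floor(sr), c0 = std::floor(sc);
      double fr = sr - r0, fc = sc - c0;
      int ri0 = reflect(r0, n), ri1 = reflect(r0 + 1, n);
      int ci0 = reflect(c0, m), ci1 = reflect(c0 + 1, m);
      out(i, j) = (1 - fr) * (1 - fc) * img(ri0, ci0) +
                  (1 - fr) * fc * img(ri0, ci1) +
                  fr * (1 - fc) * img(ri1, ci0) +
                  fr * fc * img(ri1, ci1);
    }
  }
  return out;
}
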