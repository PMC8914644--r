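// Core numeric kernels: 2-D convolution (same padding, stride 1) via
// im2col + GEMM, 2x2 max pooling, and a bilinear affine warp used for
// sprite rotation and training-time augmentation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}
static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// im2col for one image: x is (H, W, C) column-major, kernel k x k, stride 1,
// 'same' output size with replicate (edge-clamp) padding — zero padding
// would surround every scene with a dark frame that mimics insect pixels.
// Row index of the output is kh + k*(kw + k*c), matching the flattening of
// a (k, k, Cin, Cout) weight array into (k*k*Cin, Cout).
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static void im2col_same(const double* x, int H, int W, int C, int k,
                        arma::mat& cols) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * c);
        for (int w = 0; w < W; ++w) {
          const int iw = clampi(w + kw - p, 0, W - 1);
          const double* src = xc + (size_t)H * iw;
          for (int h = 0; h < H; ++h) {
            const int ih = clampi(h + kh - p, 0, H - 1);
            cols((size_t)r, (size_t)h + (size_t)H * w) = src[ih];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericMatrix Wm, NumericVector bias,
                        IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int k = (int)std::sqrt((double)(Wm.nrow() / C));
  const int Cout = Wm.ncol();
  arma::mat Wmat(Wm.begin(), Wm.nrow(), Cout, false);
  arma::vec b(bias.begin(), Cout, false);
  NumericVector out = alloc4d(H, W, Cout, N);
  arma::mat cols(Wm.nrow(), (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)H * W * C * n, H, W, C, k, cols);
    arma::mat o = cols.t() * Wmat;            // (H*W) x Cout
    o.each_row() += b.t();
    std::copy(o.begin(), o.end(), out.begin() + (size_t)H * W * Cout * n);
  }
  return out;
}

// col2im (scatter-add), inverse of im2col_same
static void col2im_same(const arma::mat& cols, int H, int W, int C, int k,
                        double* dx) {
  const int p = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * c);
        for (int w = 0; w < W; ++w) {
          const int iw = clampi(w + kw - p, 0, W - 1);
          double* dst = xc + (size_t)H * iw;
          for (int h = 0; h < H; ++h) {
            const int ih = clampi(h + kh - p, 0, H - 1);
            dst[ih] += cols((size_t)r, (size_t)h + (size_t)H * w);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericMatrix Wm, NumericVector dout,
               IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int k = (int)std::sqrt((double)(Wm.nrow() / C));
  const int Cout = Wm.ncol();
  arma::mat Wmat(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector dx = alloc4d(H, W, C, N);
  arma::mat dW(Wm.nrow(), Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(Wm.nrow(), (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)H * W * C * n, H, W, C, k, cols);
    arma::mat dmat(dout.begin() + (size_t)H * W * Cout * n,
                   (size_t)H * W, Cout, false);
    dW += cols * dmat;
    db += arma::sum(dmat, 0).t();
    arma::mat dcols = Wmat * dmat.t();        // (k2C) x (H*W)
    col2im_same(dcols, H, W, C, k, dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = NumericMatrix(Wm.nrow(), Cout, dW.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2; trailing row/col dropped for odd sizes.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = alloc4d(Ho, Wo, C, N);
  IntegerVector arg = alloc4i(Ho, Wo, C, N);   // linear index into input
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      const size_t obase = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t best = base + (size_t)(2 * h) + (size_t)H * (2 * w);
          double bv = xp[best];
          const int hh[4] = {2 * h, 2 * h + 1, 2 * h, 2 * h + 1};
          const int ww[4] = {2 * w, 2 * w, 2 * w + 1, 2 * w + 1};
          for (int t = 1; t < 4; ++t) {
            size_t idx = base + (size_t)hh[t] + (size_t)H * ww[t];
            if (xp[idx] > bv) { bv = xp[idx]; best = idx; }
          }
          op[obase + (size_t)h + (size_t)Ho * w] = bv;
          ap[obase + (size_t)h + (size_t)Ho * w] = (int)best;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector dout, IntegerVector argmax,
                          IntegerVector in_dims) {
  NumericVector dx = alloc4d(in_dims[0], in_dims[1], in_dims[2], in_dims[3]);
  const double* dp = dout.begin();
  const int* ap = argmax.begin();
  double* xp = dx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[ap[i]] += dp[i];
  return dx;
}

// Bilinear affine warp of a single-channel image. The 2x3 matrix `inv`
// maps output pixel centres (row, col, 1), 0-based, to input coordinates;
// samples outside the input are set to `fill`.
// [[Rcpp::export(name = ".warp_affine")]]
NumericMatrix warp_affine(NumericMatrix img, int h_out, int w_out,
                          NumericMatrix inv, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(h_out, w_out);
  for (int c = 0; c < w_out; ++c)
    for (int r = 0; r < h_out; ++r) {
      const double ri = inv(0, 0) * r + inv(0, 1) * c + inv(0, 2);
      const double ci = inv(1, 0) * r + inv(1, 1) * c + inv(1, 2);
      const int r0 = (int)std::floor(ri), c0 = (int)std::floor(ci);
      if (r0 < -1 || r0 >= H || c0 < -1 || c0 >= W) { out(r, c) = fill; continue; }
      const double fr = ri - r0, fc = ci - c0;
      double v = 0.0;
      const int rr[2] = {r0, r0 + 1}, cc[2] = {c0, c0 + 1};
      const double wr[2] = {1.0 - fr, fr}, wc[2] = {1.0 - fc, fc};
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i) {
          const double wt = wr[i] * wc[j];
          if (wt == 0.0) continue;
          const double px = (rr[i] < 0 || rr[i] >= H || cc[j] < 0 || cc[j] >= W)
                                ? fill : img(rr[i], cc[j]);
          v += wt * px;
        }
      out(r, c) = v;
    }
  return out;
}
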