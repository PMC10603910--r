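// Low-level CPU kernels for the segmentation networks.
// Array layout throughout: column-major R arrays dim = c(H, W, C, N)
// (rows, cols, channels, batch). Convolution weights: dim = c(k, k, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword flat4(int h, int w, int c, int n, int H, int W, int C) {
  return (arma::uword)h + (arma::uword)H * ((arma::uword)w + (arma::uword)W * ((arma::uword)c + (arma::uword)C * (arma::uword)n));
}

// im2col for same-padding stride-1 convolution: out is (k*k*Ci) x (H*W)
static void im2col(const double* x, int H, int W, int Ci, int n, int k, arma::mat& col) {
  const int pad = (k - 1) / 2;
  for (int ci = 0; ci < Ci; ++ci) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * ci;
        for (int wc = 0; wc < W; ++wc) {
          const int ws = wc + kw - pad;
          if (ws < 0 || ws >= W) {
            for (int h = 0; h < H; ++h) col(r, h + H * wc) = 0.0;
            continue;
          }
          for (int h = 0; h < H; ++h) {
            const int hs = h + kh - pad;
            col(r, h + H * wc) = (hs < 0 || hs >= H) ? 0.0
              : x[flat4(hs, ws, ci, n, H, W, Ci)];
          }
        }
      }
    }
  }
}

// col2im: scatter-add (k*k*Ci) x (H*W) back into gradient image
static void col2im(const arma::mat& col, double* gx, int H, int W, int Ci, int n, int k) {
  const int pad = (k - 1) / 2;
  for (int ci = 0; ci < Ci; ++ci) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * ci;
        for (int wc = 0; wc < W; ++wc) {
          const int ws = wc + kw - pad;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hs = h + kh - pad;
            if (hs < 0 || hs >= H) continue;
            gx[flat4(hs, ws, ci, n, H, W, Ci)] += col(r, h + H * wc);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b, int k) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int Co = dw[3];
  if (dw[0] != k || dw[1] != k || dw[2] != Ci) stop("conv2d: weight shape mismatch");
  NumericVector y(R_xlen_t(H) * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);

  const arma::mat Wc(const_cast<double*>(w.begin()), k * k * Ci, Co, false, true);
  arma::mat col(k * k * Ci, H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Ci, n, k, col);
    arma::mat Ym(y.begin() + R_xlen_t(H) * W * Co * n, H * W, Co, false, true);
    Ym = col.t() * Wc;
    for (int co = 0; co < Co; ++co) Ym.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy, int k) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int Co = dw[3];
  NumericVector gx(x.size()); gx.attr("dim") = dx;
  NumericVector gw(w.size()); gw.attr("dim") = dw;
  NumericVector gb(Co);

  const arma::mat Wc(const_cast<double*>(w.begin()), k * k * Ci, Co, false, true);
  arma::mat Gw(gw.begin(), k * k * Ci, Co, false, true);
  arma::mat col(k * k * Ci, H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Ci, n, k, col);
    const arma::mat Gy(const_cast<double*>(gy.begin()) + R_xlen_t(H) * W * Co * n,
                       H * W, Co, false, true);
    Gw += col * Gy;                       // (kkCi x HW)(HW x Co)
    arma::mat gcol = Wc * Gy.t();         // (kkCi x HW)
    col2im(gcol, gx.begin(), H, W, Ci, n, k);
    for (int co = 0; co < Co; ++co) gb[co] += arma::accu(Gy.col(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled map and 0-based flat argmax into x.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(y.size());
  idx.attr("dim") = y.attr("dim");
  R_xlen_t p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++p) {
          double best = -HUGE_VAL; arma::uword bi = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh) {
              arma::uword i = flat4(2 * ho + dh, 2 * wo + dw2, c, n, H, W, C);
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          y[p] = best; idx[p] = (double)bi;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector idx, NumericVector gy, int H, int W) {
  IntegerVector dy = gy.attr("dim");
  const int C = dy[2], N = dy[3];
  NumericVector gx(R_xlen_t(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (R_xlen_t p = 0; p < gy.size(); ++p) gx[(R_xlen_t)idx[p]] += gy[p];
  return gx;
}

struct LinW { int i0, i1; double w0, w1; };

static std::vector<LinW> bilinear_weights(int n_in, int n_out) {
  // half-pixel-centre mapping (matches the common deep-learning convention
  // of bilinear interpolation without corner alignment)
  std::vector<LinW> v(n_out);
  const double s = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) * s - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int i0 = (int)std::floor(src);
    int i1 = std::min(i0 + 1, n_in - 1);
    double w1 = src - i0;
    v[i] = { i0, i1, 1.0 - w1, w1 };
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fw(NumericVector x, int Ho, int Wo) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  std::vector<LinW> rh = bilinear_weights(H, Ho), rw = bilinear_weights(W, Wo);
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  R_xlen_t p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++p) {
          const LinW& a = rh[ho]; const LinW& b = rw[wo];
          y[p] = a.w0 * b.w0 * x[flat4(a.i0, b.i0, c, n, H, W, C)]
               + a.w1 * b.w0 * x[flat4(a.i1, b.i0, c, n, H, W, C)]
               + a.w0 * b.w1 * x[flat4(a.i0, b.i1, c, n, H, W, C)]
               + a.w1 * b.w1 * x[flat4(a.i1, b.i1, c, n, H, W, C)];
        }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bw(NumericVector gy, int H, int W) {
  IntegerVector dy = gy.attr("dim");
  const int Ho = dy[0], Wo = dy[1], C = dy[2], N = dy[3];
  std::vector<LinW> rh = bilinear_weights(H, Ho), rw = bilinear_weights(W, Wo);
  NumericVector gx(R_xlen_t(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  R_xlen_t p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++p) {
          const LinW& a = rh[ho]; const LinW& b = rw[wo];
          const double g = gy[p];
          gx[flat4(a.i0, b.i0, c, n, H, W, C)] += a.w0 * b.w0 * g;
          gx[flat4(a.i1, b.i0, c, n, H, W, C)] += a.w1 * b.w0 * g;
          gx[flat4(a.i0, b.i1, c, n, H, W, C)] += a.w0 * b.w1 * g;
          gx[flat4(a.i1, b.i1, c, n, H, W, C)] += a.w1 * b.w1 * g;
        }
  return gx;
}
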