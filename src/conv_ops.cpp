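// Convolution and max-pooling kernels for the shallow CNN.
// Array layout follows R column-major order throughout: images are
// (H, W, C, N), filter banks are (k, k, C_in, C_out).  Convolutions use
// zero ("same") padding of (k-1)/2 and are computed per image via
// im2col + GEMM so the heavy lifting lands in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather the k*k*C patch matrix for one image.  Column r of the result
// corresponds to weight entry (ki, kj, c) with r = ki + k*kj + k*k*c,
// matching the column-major layout of an R (k, k, C, F) filter array.
static arma::mat im2col(const double* x, int H, int W, int C,
                        int k, int s, int p, int OH, int OW) {
  arma::mat col(OH * OW, k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int r = ki + k * kj + k * k * c;
        double* dst = col.colptr(r);
        for (int ox = 0; ox < OW; ++ox) {
          int ix = ox * s - p + kj;
          bool xin = (ix >= 0 && ix < W);
          const double* xcol = xc + (std::size_t)ix * H;
          for (int oy = 0; oy < OH; ++oy) {
            int iy = oy * s - p + ki;
            dst[oy + (std::size_t)ox * OH] =
                (xin && iy >= 0 && iy < H) ? xcol[iy] : 0.0;
          }
        }
      }
    }
  }
  return col;
}

static void out_dims(int H, int W, int k, int s, int& p, int& OH, int& OW) {
  p = (k - 1) / 2;
  OH = (H + 2 * p - k) / s + 1;
  OW = (W + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], F = wd[3];
  if (wd[2] != C) stop("filter input channels do not match image channels");
  int p, OH, OW;
  out_dims(H, W, k, stride, p, OH, OW);
  if (OH < 1 || OW < 1) stop("image too small for this kernel/stride");

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, F, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), F, false, true);

  NumericVector y((R_xlen_t)OH * OW * F * N);
  y.attr("dim") = IntegerVector::create(OH, OW, F, N);
  std::size_t ysz = (std::size_t)OH * OW * F;
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (std::size_t)n * H * W * C,
                           H, W, C, k, stride, p, OH, OW);
    arma::mat out = col * Wm;       // (OH*OW) x F
    out.each_row() += bv;
    std::copy(out.memptr(), out.memptr() + ysz, y.begin() + n * ysz);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w,
                         NumericVector dy, int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], F = wd[3];
  int p, OH, OW;
  out_dims(H, W, k, stride, p, OH, OW);

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, F, false, true);
  arma::mat dW(k * k * C, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);

  std::size_t ysz = (std::size_t)OH * OW * F;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)n * H * W * C;
    arma::mat col = im2col(xn, H, W, C, k, stride, p, OH, OW);
    arma::mat dyn(const_cast<double*>(dy.begin()) + n * ysz,
                  OH * OW, F, false, true);
    dW += col.t() * dyn;
    db += arma::sum(dyn, 0);
    arma::mat dcol = dyn * Wm.t();  // (OH*OW) x (k*k*C)
    double* dxn = dx.begin() + (std::size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (std::size_t)c * H * W;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          int r = ki + k * kj + k * k * c;
          const double* src = dcol.colptr(r);
          for (int ox = 0; ox < OW; ++ox) {
            int ix = ox * stride - p + kj;
            if (ix < 0 || ix >= W) continue;
            double* dxcol = dxc + (std::size_t)ix * H;
            for (int oy = 0; oy < OH; ++oy) {
              int iy = oy * stride - p + ki;
              if (iy < 0 || iy >= H) continue;
              dxcol[iy] += src[oy + (std::size_t)ox * OH];
            }
          }
        }
      }
    }
  }

  NumericVector dwr(wd[0] * wd[1] * wd[2] * wd[3]);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dwr.begin());
  dwr.attr("dim") = wd;
  NumericVector dbr(F);
  std::copy(db.memptr(), db.memptr() + F, dbr.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwr, _["db"] = dbr);
}

// Max pooling with window q x q, stride q (non-overlapping); trailing
// rows/columns that do not fill a window are dropped, as in Keras.
// idx records the 0-based linear index (within the whole input array)
// of each pooled maximum, so the backward pass is a pure scatter.
// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int q) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = H / q, OW = W / q;
  if (OH < 1 || OW < 1) stop("image too small for pooling window");

  NumericVector y((R_xlen_t)OH * OW * C * N);
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  IntegerVector idx((R_xlen_t)OH * OW * C * N);
  idx.attr("dim") = IntegerVector::create(OH, OW, C, N);
  std::size_t t = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      std::size_t base = (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int ox = 0; ox < OW; ++ox) {
        for (int oy = 0; oy < OH; ++oy) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t besti = 0;
          for (int dj = 0; dj < q; ++dj) {
            for (int di = 0; di < q; ++di) {
              std::size_t ii = base + (std::size_t)(oy * q + di) +
                               (std::size_t)H * (ox * q + dj);
              double v = x[ii];
              if (v > best) { best = v; besti = ii; }
            }
          }
          // y/idx are filled in (oy, ox, c, n) column-major order, but the
          // loop nest above runs ox outside oy, so index explicitly.
          std::size_t yo = (std::size_t)oy + (std::size_t)OH * ox +
                           (std::size_t)OH * OW * (c + (std::size_t)C * n);
          y[yo] = best;
          idx[yo] = (int)besti;
          ++t;
        }
      }
    }
  }
  (void)t;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  NumericVector dx((std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  R_xlen_t m = dy.size();
  for (R_xlen_t i = 0; i < m; ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}
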