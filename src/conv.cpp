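// Convolution forward/backward via im2col + GEMM (Armadillo).
//
// Array layouts follow R's column-major order:
//   activations x : (H, W, C, N)
//   weights     w : (f, f, Cin, K)   -- flattens to (f*f*Cin) x K
//   outputs     y : (Ho, Wo, K, N)   -- per-sample slice is (Ho*Wo) x K
// so per-sample GEMMs work directly on memory views without copies.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline void getDims(const Rcpp::NumericVector &a, int d[4]) {
  Rcpp::IntegerVector dim = a.attr("dim");
  if (dim.size() != 4) Rcpp::stop("expected a 4-D array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// Fill cols (f*f*C x Ho*Wo) from sample n of x, with zero padding.
static void im2col(const double *x, int H, int W, int C,
                   int f, int stride, int pad, int Ho, int Wo, mat &cols) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * H * W;
    for (int fw = 0; fw < f; ++fw) {
      for (int fh = 0; fh < f; ++fh) {
        int r = fh + f * fw + f * f * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + fw;
          if (wi < 0 || wi >= W) continue;
          const double *col = xc + (size_t)wi * H;
          double *dst = cols.memptr() + (size_t)r +
                        (size_t)cols.n_rows * ((size_t)Ho * wo);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + fh;
            if (hi >= 0 && hi < H)
              dst[(size_t)ho * cols.n_rows] = col[hi];
          }
        }
      }
    }
  }
}

// Scatter cols (f*f*C x Ho*Wo) back into sample n of dx (accumulating).
static void col2im(const mat &cols, int H, int W, int C,
                   int f, int stride, int pad, int Ho, int Wo, double *dx) {
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (size_t)c * H * W;
    for (int fw = 0; fw < f; ++fw) {
      for (int fh = 0; fh < f; ++fh) {
        int r = fh + f * fw + f * f * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + fw;
          if (wi < 0 || wi >= W) continue;
          double *col = xc + (size_t)wi * H;
          const double *src = cols.memptr() + (size_t)r +
                              (size_t)cols.n_rows * ((size_t)Ho * wo);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + fh;
            if (hi >= 0 && hi < H)
              col[hi] += src[(size_t)ho * cols.n_rows];
          }
        }
      }
    }
  }
}

static inline int outSize(int n, int p, int f, int s) {
  int o = (n + 2 * p - f) / s + 1;
  if (o <= 0) Rcpp::stop("non-positive convolution output size");
  return o;
}

// [[Rcpp::export(name = ".convForward")]]
Rcpp::NumericVector convForward(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                Rcpp::NumericVector b, int stride, int pad) {
  int dx[4], dw[4];
  getDims(x, dx); getDims(w, dw);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int f = dw[0], K = dw[3];
  if (dw[1] != f || dw[2] != C) Rcpp::stop("weight dims do not match input");
  int Ho = outSize(H, pad, f, stride), Wo = outSize(W, pad, f, stride);
  Rcpp::NumericVector y((R_xlen_t)Ho * Wo * K * N);
  y.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, K, N);
  const mat Wm(const_cast<double *>(w.begin()), f * f * C, K, false, true);
  const rowvec bv(const_cast<double *>(b.begin()), K, false, true);
  mat cols(f * f * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, f, stride, pad,
           Ho, Wo, cols);
    mat yn(y.begin() + (size_t)n * Ho * Wo * K, Ho * Wo, K, false, true);
    yn = cols.t() * Wm;
    yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".convBackward")]]
Rcpp::List convBackward(Rcpp::NumericVector x, Rcpp::NumericVector w,
                        Rcpp::NumericVector dy, int stride, int pad) {
  int dxd[4], dwd[4], dyd[4];
  getDims(x, dxd); getDims(w, dwd); getDims(dy, dyd);
  int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  int f = dwd[0], K = dwd[3];
  int Ho = dyd[0], Wo = dyd[1];
  if (dyd[2] != K || dyd[3] != N) Rcpp::stop("dy dims do not match");
  Rcpp::NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  Rcpp::NumericVector dwOut((R_xlen_t)f * f * C * K);
  dwOut.attr("dim") = Rcpp::IntegerVector::create(f, f, C, K);
  Rcpp::NumericVector dbOut(K);
  const mat Wm(const_cast<double *>(w.begin()), f * f * C, K, false, true);
  mat dWm(dwOut.begin(), f * f * C, K, false, true);
  vec dbv(dbOut.begin(), K, false, true);
  mat cols(f * f * C, Ho * Wo), dcols(f * f * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const mat dyn(const_cast<double *>(dy.begin()) + (size_t)n * Ho * Wo * K,
                  Ho * Wo, K, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, f, stride, pad,
           Ho, Wo, cols);
    dWm += cols * dyn;
    dbv += sum(dyn, 0).t();
    dcols = Wm * dyn.t();
    col2im(dcols, H, W, C, f, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dwOut,
                            Rcpp::Named("db") = dbOut);
}
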