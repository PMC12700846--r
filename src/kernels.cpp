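// Dense compute kernels backing the autograd engine.
//
// Tensors cross the R/C++ boundary as base R numeric arrays in (b, c, h, w)
// order (R is column-major, so b varies fastest).  Each kernel copies the
// per-slice data it needs into a contiguous buffer once, then expresses the
// heavy arithmetic as a BLAS gemm via Armadillo (im2col / col2im for
// convolutions).  Everything is double precision.

#include <RcppArmadillo.h>
#ifndef FCONE
#define USE_FC_LEN_T
#endif
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void blas_dgemm(char ta, char tb, int m, int n, int k,
                              double alpha, const double* A, int lda,
                              const double* B, int ldb, double beta,
                              double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

// R's BLAS headers only declare double routines; the linked BLAS library
// provides the full set, so declare sgemm with gfortran's hidden
// string-length arguments.
extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*, size_t, size_t);

static inline void blas_sgemm(char ta, char tb, int m, int n, int k,
                              float alpha, const float* A, int lda,
                              const float* B, int ldb, float beta,
                              float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc,
         1, 1);
}

// Large stride-1 convolutions run in float32: they are memory-bandwidth
// bound, the halved traffic roughly doubles throughput, and training
// tolerates single precision.  Small problems (every oracle/gradcheck
// fixture) keep full double precision.
static inline bool conv_use_float(size_t M, int CIG, int COG, int KH, int KW,
                                  int groups) {
  return (double)M * CIG * COG * KH * KW * groups >= 1e7;
}

static inline int out_extent(int in, int k, int s, int p, int d) {
  return (in + 2 * p - d * (k - 1) - 1) / s + 1;
}

// View x (B,C,H,W; column-major, b fastest) as a (B*C, H*W) matrix and
// transpose it once (blocked, fast) so that image b's pixels-by-channels
// matrix is a cheap contiguous column gather: xs_all has layout
// (H*W, B*C) with column index b + B*c.
static arma::mat to_pixel_major(const double* x, int B, int C, int HW) {
  arma::mat Xm(const_cast<double*>(x), (size_t)B * C, HW, false, true);
  return Xm.t();
}

static void gather_slice(const arma::mat& xs_all, int b, int B, int C,
                         arma::mat& xs) {
  for (int c = 0; c < C; ++c) xs.col(c) = xs_all.col(b + (size_t)B * c);
}

static void scatter_slice(arma::mat& ys_all, int b, int B, int C,
                          const arma::mat& ys) {
  for (int c = 0; c < C; ++c) ys_all.col(b + (size_t)B * c) = ys.col(c);
}

// im2col, transposed layout: colsT is (HO*WO, CIG*KH*KW) so both the reads
// from xs (pixel-major, contiguous in h) and the writes (contiguous down a
// column) stream through memory.  Column order: ci + CIG*(kh + KH*kw),
// matching the column-major reshape of a weight array (CO, CIG, KH, KW).
static void im2col_t(const arma::mat& xs, int H, int W, int c0, int CIG,
                     int KH, int KW, int s, int p, int d,
                     int HO, int WO, arma::mat& colsT) {
  for (int kw = 0; kw < KW; ++kw) {
    for (int kh = 0; kh < KH; ++kh) {
      for (int ci = 0; ci < CIG; ++ci) {
        int r = ci + CIG * (kh + KH * kw);
        const double* xc = xs.colptr(c0 + ci);
        double* dst = colsT.colptr(r);
        for (int ow = 0; ow < WO; ++ow) {
          int wi = ow * s - p + kw * d;
          double* dcol = dst + (size_t)HO * ow;
          if (wi < 0 || wi >= W) {
            for (int oh = 0; oh < HO; ++oh) dcol[oh] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * wi;
          if (s == 1 && p == 0 && KH == 1) {
            memcpy(dcol, src, sizeof(double) * HO);
          } else {
            for (int oh = 0; oh < HO; ++oh) {
              int hi = oh * s - p + kh * d;
              dcol[oh] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im_t(const arma::mat& colsT, int H, int W, int c0, int CIG,
                     int KH, int KW, int s, int p, int d,
                     int HO, int WO, arma::mat& xs) {
  for (int kw = 0; kw < KW; ++kw) {
    for (int kh = 0; kh < KH; ++kh) {
      for (int ci = 0; ci < CIG; ++ci) {
        int r = ci + CIG * (kh + KH * kw);
        double* xc = xs.colptr(c0 + ci);
        const double* src = colsT.colptr(r);
        for (int ow = 0; ow < WO; ++ow) {
          int wi = ow * s - p + kw * d;
          if (wi < 0 || wi >= W) continue;
          const double* scol = src + (size_t)HO * ow;
          double* xcol = xc + (size_t)H * wi;
          for (int oh = 0; oh < HO; ++oh) {
            int hi = oh * s - p + kh * d;
            if (hi >= 0 && hi < H) xcol[hi] += scol[oh];
          }
        }
      }
    }
  }
}

// Stride-1 implicit-gemm convolution, whole batch at once: all B padded
// slices are stacked as rows of Xbig ((B * Hp * Wp) x C, pixel-major), and
// each kernel tap contributes one strided-view BLAS gemm against its
// (CO x C) weight slice.  No im2col buffer is materialized.  Because valid
// output rows never reach past their own slice (the maximal in-slice shift
// lands exactly on the slice's last row), tap shifts only pollute garbage
// rows, which the callers crop.  Rows are processed in chunks so the output
// chunk stays cache-resident across all taps.
static const int CONV_CHUNK = 2048;

static inline void gemm_any(char ta, char tb, int m, int n, int k,
                            const double* A, int lda, const double* B, int ldb,
                            double* C, int ldc) {
  blas_dgemm(ta, tb, m, n, k, 1.0, A, lda, B, ldb, 1.0, C, ldc);
}
static inline void gemm_any(char ta, char tb, int m, int n, int k,
                            const float* A, int lda, const float* B, int ldb,
                            float* C, int ldc) {
  blas_sgemm(ta, tb, m, n, k, 1.0f, A, lda, B, ldb, 1.0f, C, ldc);
}

template <typename T>
static void conv_big_fwd_s1(const arma::Mat<T>& xbig, const arma::Mat<T>& wmat,
                            int CO, int CIG, int KH, int KW, int dil,
                            int groups, int hstride, int wstride,
                            arma::Mat<T>& ybig) {
  int M = xbig.n_rows;
  int COG = CO / groups;
  ybig.zeros();
  for (int r0 = 0; r0 < M; r0 += CONV_CHUNK) {
    int r1 = std::min(M, r0 + CONV_CHUNK);
    for (int g = 0; g < groups; ++g)
      for (int kw = 0; kw < KW; ++kw)
        for (int kh = 0; kh < KH; ++kh) {
          int off = kh * dil * hstride + kw * dil * wstride;
          int m = std::min(r1, M - off) - r0;
          if (m <= 0) continue;
          const T* B =
              wmat.memptr() + (size_t)g * COG + (size_t)CO * CIG * (kh + KH * kw);
          gemm_any('N', 'T', m, COG, CIG,
                   xbig.colptr(g * CIG) + r0 + off, M, B, CO,
                   ybig.colptr(g * COG) + r0, M);
        }
  }
}

template <typename T>
static void conv_big_bwd_s1(const arma::Mat<T>& xbig, const arma::Mat<T>& gybig,
                            const arma::Mat<T>& wmat, arma::Mat<T>& gwmat,
                            int CO, int CIG, int KH, int KW, int dil,
                            int groups, int hstride, int wstride,
                            arma::Mat<T>& gxbig) {
  int M = xbig.n_rows;
  int COG = CO / groups;
  for (int r0 = 0; r0 < M; r0 += CONV_CHUNK) {
    int r1 = std::min(M, r0 + CONV_CHUNK);
    for (int g = 0; g < groups; ++g)
      for (int kw = 0; kw < KW; ++kw)
        for (int kh = 0; kh < KH; ++kh) {
          int off = kh * dil * hstride + kw * dil * wstride;
          int m = std::min(r1, M - off) - r0;
          if (m <= 0) continue;
          const T* B =
              wmat.memptr() + (size_t)g * COG + (size_t)CO * CIG * (kh + KH * kw);
          T* GB = gwmat.memptr() + (size_t)g * COG +
                  (size_t)CO * CIG * (kh + KH * kw);
          // gX[r + off, ci] += gY[r, co] * W[co, ci]
          gemm_any('N', 'N', m, CIG, COG, gybig.colptr(g * COG) + r0,
                   M, B, CO, gxbig.colptr(g * CIG) + r0 + off, M);
          // gW[co, ci] += sum_r gY[r, co] * X[r + off, ci]
          gemm_any('T', 'N', COG, CIG, m, gybig.colptr(g * COG) + r0,
                   M, xbig.colptr(g * CIG) + r0 + off, M, GB, CO);
        }
  }
}

template <typename T>
static void conv_fwd_s1_run(const NumericVector& x, const NumericVector& w,
                            const NumericVector& bias, int B, int C, int H,
                            int W, int CO, int CIG, int KH, int KW, int dil,
                            int groups, int pad, int HO, int WO,
                            NumericVector& y) {
  int Hp = H + 2 * pad, Wp = W + 2 * pad;
  size_t M = (size_t)B * Hp * Wp;
  arma::Mat<T> xbig(M, C, arma::fill::zeros);
  arma::Mat<T> ybig(M, CO);
  arma::Mat<T> wmat(CO, (size_t)CIG * KH * KW);
  for (size_t i = 0; i < wmat.n_elem; ++i) wmat[i] = (T)w[i];
  for (int c = 0; c < C; ++c) {
    T* dst = xbig.colptr(c);
    const double* src = x.begin() + (size_t)B * c;
    for (int wI = 0; wI < W; ++wI)
      for (int hI = 0; hI < H; ++hI) {
        T* d2 = dst + (size_t)B * ((hI + pad) + (size_t)Hp * (wI + pad));
        const double* s2 = src + (size_t)B * C * (hI + (size_t)H * wI);
        for (int b = 0; b < B; ++b) d2[b] = (T)s2[b];
      }
  }
  conv_big_fwd_s1(xbig, wmat, CO, CIG, KH, KW, dil, groups, B, B * Hp, ybig);
  for (int o = 0; o < CO; ++o) {
    double bo = bias[o];
    const T* src = ybig.colptr(o);
    double* dst = y.begin() + (size_t)B * o;
    for (int ow = 0; ow < WO; ++ow)
      for (int oh = 0; oh < HO; ++oh) {
        const T* s2 = src + (size_t)B * (oh + (size_t)Hp * ow);
        double* d2 = dst + (size_t)B * CO * (oh + (size_t)HO * ow);
        for (int b = 0; b < B; ++b) d2[b] = (double)s2[b] + bo;
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad,
                             int dilation, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int CO = wd[0], CIG = wd[1], KH = wd[2], KW = wd[3];
  if (C != CIG * groups) stop("conv2d: input channels do not match weights");
  if (CO % groups != 0) stop("conv2d: output channels not divisible by groups");
  int COG = CO / groups;
  int HO = out_extent(H, KH, stride, pad, dilation);
  int WO = out_extent(W, KW, stride, pad, dilation);
  if (HO < 1 || WO < 1) stop("conv2d: output extent would be empty");

  NumericVector y((size_t)B * CO * HO * WO);
  y.attr("dim") = IntegerVector::create(B, CO, HO, WO);
  arma::mat Wall(const_cast<double*>(w.begin()), CO, (size_t)CIG * KH * KW,
                 false, true);
  if (stride == 1) {
    // batch-interleaved pixel-major rows: r = b + B*(hp + Hp*wp), so every
    // copy between the (B,C,H,W) R array and the gemm operand is contiguous,
    // and tap shifts are multiples of B.
    int Hp = H + 2 * pad, Wp = W + 2 * pad;
    size_t M = (size_t)B * Hp * Wp;
    if (conv_use_float(M, CIG, COG, KH, KW, groups)) {
      conv_fwd_s1_run<float>(x, w, bias, B, C, H, W, CO, CIG, KH, KW,
                             dilation, groups, pad, HO, WO, y);
    } else {
      conv_fwd_s1_run<double>(x, w, bias, B, C, H, W, CO, CIG, KH, KW,
                              dilation, groups, pad, HO, WO, y);
    }
    return y;
  }
  arma::mat xs_all = to_pixel_major(x.begin(), B, C, H * W);
  arma::mat ys_all((size_t)HO * WO, (size_t)B * CO);
  arma::mat ys(HO * WO, CO);
  arma::mat xs(H * W, C), colsT((size_t)HO * WO, (size_t)CIG * KH * KW);
  for (int b = 0; b < B; ++b) {
    gather_slice(xs_all, b, B, C, xs);
    for (int g = 0; g < groups; ++g) {
      im2col_t(xs, H, W, g * CIG, CIG, KH, KW, stride, pad, dilation, HO, WO,
               colsT);
      arma::mat Wg = Wall.rows(g * COG, (g + 1) * COG - 1);
      ys.cols(g * COG, (g + 1) * COG - 1) = colsT * Wg.t(); // (HO*WO, COG)
      for (int o = 0; o < COG; ++o) {
        double bo = bias[g * COG + o];
        double* dst = ys.colptr(g * COG + o);
        for (int l = 0; l < HO * WO; ++l) dst[l] += bo;
      }
    }
    scatter_slice(ys_all, b, B, CO, ys);
  }
  arma::mat Ym(y.begin(), (size_t)B * CO, (size_t)HO * WO, false, true);
  Ym = ys_all.t();
  return y;
}

template <typename T>
static void conv_bwd_s1_run(const NumericVector& x, const NumericVector& w,
                            const NumericVector& gout, int B, int C, int H,
                            int W, int CO, int CIG, int KH, int KW, int dil,
                            int groups, int pad, int HO, int WO,
                            NumericVector& gx, NumericVector& gw,
                            NumericVector& gb) {
  int Hp = H + 2 * pad, Wp = W + 2 * pad;
  size_t M = (size_t)B * Hp * Wp;
  arma::Mat<T> xbig(M, C, arma::fill::zeros);
  arma::Mat<T> gybig(M, CO, arma::fill::zeros);
  arma::Mat<T> gxbig(M, C, arma::fill::zeros);
  arma::Mat<T> wmat(CO, (size_t)CIG * KH * KW);
  arma::Mat<T> gwmat(CO, (size_t)CIG * KH * KW, arma::fill::zeros);
  for (size_t i = 0; i < wmat.n_elem; ++i) wmat[i] = (T)w[i];
  for (int c = 0; c < C; ++c) {
    T* dst = xbig.colptr(c);
    const double* src = x.begin() + (size_t)B * c;
    for (int wI = 0; wI < W; ++wI)
      for (int hI = 0; hI < H; ++hI) {
        T* d2 = dst + (size_t)B * ((hI + pad) + (size_t)Hp * (wI + pad));
        const double* s2 = src + (size_t)B * C * (hI + (size_t)H * wI);
        for (int b = 0; b < B; ++b) d2[b] = (T)s2[b];
      }
  }
  for (int o = 0; o < CO; ++o) {
    T* dst = gybig.colptr(o);
    const double* src = gout.begin() + (size_t)B * o;
    double s = 0.0;
    for (int ow = 0; ow < WO; ++ow)
      for (int oh = 0; oh < HO; ++oh) {
        const double* s2 = src + (size_t)B * CO * (oh + (size_t)HO * ow);
        T* d2 = dst + (size_t)B * (oh + (size_t)Hp * ow);
        for (int b = 0; b < B; ++b) {
          d2[b] = (T)s2[b];
          s += s2[b];
        }
      }
    gb[o] = s;
  }
  conv_big_bwd_s1(xbig, gybig, wmat, gwmat, CO, CIG, KH, KW, dil, groups,
                  B, B * Hp, gxbig);
  for (size_t i = 0; i < gwmat.n_elem; ++i) gw[i] = (double)gwmat[i];
  for (int c = 0; c < C; ++c) {
    const T* src = gxbig.colptr(c);
    double* dst = gx.begin() + (size_t)B * c;
    for (int wI = 0; wI < W; ++wI)
      for (int hI = 0; hI < H; ++hI) {
        double* d2 = dst + (size_t)B * C * (hI + (size_t)H * wI);
        const T* s2 = src + (size_t)B * ((hI + pad) + (size_t)Hp * (wI + pad));
        for (int b = 0; b < B; ++b) d2[b] = (double)s2[b];
      }
  }
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                    int stride, int pad, int dilation, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int CO = wd[0], CIG = wd[1], KH = wd[2], KW = wd[3];
  int COG = CO / groups;
  int HO = out_extent(H, KH, stride, pad, dilation);
  int WO = out_extent(W, KW, stride, pad, dilation);

  NumericVector gx((size_t)B * C * H * W);
  gx.attr("dim") = IntegerVector::create(B, C, H, W);
  NumericVector gw((size_t)CO * CIG * KH * KW);
  gw.attr("dim") = IntegerVector::create(CO, CIG, KH, KW);
  NumericVector gb(CO);

  arma::mat Wall(const_cast<double*>(w.begin()), CO, (size_t)CIG * KH * KW,
                 false, true);
  arma::mat GWall(gw.begin(), CO, (size_t)CIG * KH * KW, false, true);
  if (stride == 1) {
    size_t M = (size_t)B * (H + 2 * pad) * (W + 2 * pad);
    if (conv_use_float(M, CIG, COG, KH, KW, groups)) {
      conv_bwd_s1_run<float>(x, w, gout, B, C, H, W, CO, CIG, KH, KW,
                             dilation, groups, pad, HO, WO, gx, gw, gb);
    } else {
      conv_bwd_s1_run<double>(x, w, gout, B, C, H, W, CO, CIG, KH, KW,
                              dilation, groups, pad, HO, WO, gx, gw, gb);
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat xs_all = to_pixel_major(x.begin(), B, C, H * W);
  arma::mat gys_all = to_pixel_major(gout.begin(), B, CO, HO * WO);
  arma::mat gxs_all((size_t)H * W, (size_t)B * C);
  {
    arma::mat xs(H * W, C), gxs(H * W, C);
    arma::mat colsT((size_t)HO * WO, (size_t)CIG * KH * KW);
    arma::mat gcolsT((size_t)HO * WO, (size_t)CIG * KH * KW);
    arma::mat gys(HO * WO, CO);
    for (int b = 0; b < B; ++b) {
      gather_slice(xs_all, b, B, C, xs);
      gather_slice(gys_all, b, B, CO, gys);
      gxs.zeros();
      for (int g = 0; g < groups; ++g) {
        im2col_t(xs, H, W, g * CIG, CIG, KH, KW, stride, pad, dilation, HO, WO,
                 colsT);
        arma::mat gys_g = gys.cols(g * COG, (g + 1) * COG - 1); // (HO*WO, COG)
        for (int o = 0; o < COG; ++o) gb[g * COG + o] += arma::accu(gys_g.col(o));
        GWall.rows(g * COG, (g + 1) * COG - 1) += gys_g.t() * colsT;
        arma::mat Wg = Wall.rows(g * COG, (g + 1) * COG - 1);
        gcolsT = gys_g * Wg;
        col2im_t(gcolsT, H, W, g * CIG, CIG, KH, KW, stride, pad, dilation,
                 HO, WO, gxs);
      }
      scatter_slice(gxs_all, b, B, C, gxs);
    }
  }
  arma::mat GXm(gx.begin(), (size_t)B * C, (size_t)H * W, false, true);
  GXm = gxs_all.t();
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling with stride 2; returns pooled values and flat argmax
// indices (1-based into the input vector) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int HO = H / 2, WO = W / 2;
  size_t BC = (size_t)B * C;
  NumericVector y(BC * HO * WO);
  y.attr("dim") = IntegerVector::create(B, C, HO, WO);
  IntegerVector idx(BC * HO * WO);
  const double* xp = x.begin();
  for (int w = 0; w < WO; ++w)
    for (int h = 0; h < HO; ++h) {
      size_t obase = BC * (h + (size_t)HO * w);
      for (int dw = 0; dw < 2; ++dw)
        for (int dh = 0; dh < 2; ++dh) {
          size_t ibase = BC * ((2 * h + dh) + (size_t)H * (2 * w + dw));
          if (dh == 0 && dw == 0) {
            for (size_t j = 0; j < BC; ++j) {
              y[obase + j] = xp[ibase + j];
              idx[obase + j] = (int)(ibase + j + 1);
            }
          } else {
            for (size_t j = 0; j < BC; ++j) {
              if (xp[ibase + j] > y[obase + j]) {
                y[obase + j] = xp[ibase + j];
                idx[obase + j] = (int)(ibase + j + 1);
              }
            }
          }
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gout,
                               IntegerVector in_dim) {
  NumericVector gx((size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  gx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[idx[i] - 1] += gout[i];
  return gx;
}

// Average pooling with kernel = stride = k (the patch-embedding primitive).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int HO = H / k, WO = W / k;
  NumericVector y((size_t)B * C * HO * WO);
  y.attr("dim") = IntegerVector::create(B, C, HO, WO);
  double inv = 1.0 / (k * k);
  size_t BC = (size_t)B * C;
  for (int w = 0; w < WO; ++w)
    for (int h = 0; h < HO; ++h) {
      size_t obase = BC * (h + (size_t)HO * w);
      for (int dw = 0; dw < k; ++dw)
        for (int dh = 0; dh < k; ++dh) {
          size_t ibase = BC * ((k * h + dh) + (size_t)H * (k * w + dw));
          for (size_t j = 0; j < BC; ++j) y[obase + j] += x[ibase + j];
        }
      for (size_t j = 0; j < BC; ++j) y[obase + j] *= inv;
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector gout, int k, IntegerVector in_dim) {
  int B = in_dim[0], C = in_dim[1], H = in_dim[2], W = in_dim[3];
  int HO = H / k, WO = W / k;
  NumericVector gx((size_t)B * C * H * W);
  gx.attr("dim") = in_dim;
  double inv = 1.0 / (k * k);
  size_t BC = (size_t)B * C;
  for (int w = 0; w < WO; ++w)
    for (int h = 0; h < HO; ++h) {
      size_t obase = BC * (h + (size_t)HO * w);
      for (int dw = 0; dw < k; ++dw)
        for (int dh = 0; dh < k; ++dh) {
          size_t ibase = BC * ((k * h + dh) + (size_t)H * (k * w + dw));
          for (size_t j = 0; j < BC; ++j) gx[ibase + j] += gout[obase + j] * inv;
        }
    }
  return gx;
}

// Bilinear resize with half-pixel centers (align_corners = FALSE).
static inline void bil_coef(int o, int in, double scale, int& i0, int& i1,
                            double& w1) {
  double src = (o + 0.5) * scale - 0.5;
  if (src < 0) src = 0;
  if (src > in - 1) src = in - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, in - 1);
  w1 = src - i0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int HO, int WO) {
  IntegerVector xd = x.attr("dim");
  int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y((size_t)B * C * HO * WO);
  y.attr("dim") = IntegerVector::create(B, C, HO, WO);
  double sh = (double)H / HO, sw = (double)W / WO;
  size_t BC = (size_t)B * C;
  for (int ow = 0; ow < WO; ++ow) {
    int w0, w1i; double ww;
    bil_coef(ow, W, sw, w0, w1i, ww);
    for (int oh = 0; oh < HO; ++oh) {
      int h0, h1i; double wh;
      bil_coef(oh, H, sh, h0, h1i, wh);
      const double* p00 = x.begin() + BC * (h0 + (size_t)H * w0);
      const double* p10 = x.begin() + BC * (h1i + (size_t)H * w0);
      const double* p01 = x.begin() + BC * (h0 + (size_t)H * w1i);
      const double* p11 = x.begin() + BC * (h1i + (size_t)H * w1i);
      double* out = y.begin() + BC * (oh + (size_t)HO * ow);
      double a = (1 - wh) * (1 - ww), bq = wh * (1 - ww);
      double cq = (1 - wh) * ww, dq = wh * ww;
      for (size_t j = 0; j < BC; ++j)
        out[j] = a * p00[j] + bq * p10[j] + cq * p01[j] + dq * p11[j];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector gout, int H, int W) {
  IntegerVector gd = gout.attr("dim");
  int B = gd[0], C = gd[1], HO = gd[2], WO = gd[3];
  NumericVector gx((size_t)B * C * H * W);
  gx.attr("dim") = IntegerVector::create(B, C, H, W);
  double sh = (double)H / HO, sw = (double)W / WO;
  size_t BC = (size_t)B * C;
  for (int ow = 0; ow < WO; ++ow) {
    int w0, w1i; double ww;
    bil_coef(ow, W, sw, w0, w1i, ww);
    for (int oh = 0; oh < HO; ++oh) {
      int h0, h1i; double wh;
      bil_coef(oh, H, sh, h0, h1i, wh);
      double* p00 = gx.begin() + BC * (h0 + (size_t)H * w0);
      double* p10 = gx.begin() + BC * (h1i + (size_t)H * w0);
      double* p01 = gx.begin() + BC * (h0 + (size_t)H * w1i);
      double* p11 = gx.begin() + BC * (h1i + (size_t)H * w1i);
      const double* g = gout.begin() + BC * (oh + (size_t)HO * ow);
      double a = (1 - wh) * (1 - ww), bq = wh * (1 - ww);
      double cq = (1 - wh) * ww, dq = wh * ww;
      for (size_t j = 0; j < BC; ++j) {
        p00[j] += a * g[j];
        p10[j] += bq * g[j];
        p01[j] += cq * g[j];
        p11[j] += dq * g[j];
      }
    }
  }
  return gx;
}

// Mean of nearest-neighbour distances from each row of `a` to the rows of
// `b`; coordinates are already scaled to physical units by the caller.
// [[Rcpp::export]]
double cpp_mean_nn_dist(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow(), d = a.ncol();
  if (na == 0 || nb == 0) return NA_REAL;
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = INFINITY;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = a(i, k) - b(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    total += std::sqrt(best);
  }
  return total / na;
}

// Batched matrix multiply: out[i,,] = x[i,,] %*% y[i,,] for 3-d arrays
// sharing the leading (batch) index; transa/transb transpose the per-slice
// matrices.  Slices are gathered into contiguous buffers (the leading index
// varies fastest in R's column-major layout) and multiplied via BLAS.
// [[Rcpp::export]]
NumericVector cpp_bmm(NumericVector x, NumericVector y, bool transa,
                      bool transb) {
  IntegerVector xd = x.attr("dim"), yd = y.attr("dim");
  int n = xd[0];
  int xr = xd[1], xc = xd[2], yr = yd[1], yc = yd[2];
  int m = transa ? xc : xr;
  int k = transa ? xr : xc;
  int k2 = transb ? yc : yr;
  int p = transb ? yr : yc;
  if (n != yd[0] || k != k2) stop("bmm: non-conformable shapes");
  NumericVector out((size_t)n * m * p);
  out.attr("dim") = IntegerVector::create(n, m, p);
  arma::mat A(xr, xc), Bm(yr, yc), Cm(m, p);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < xc; ++c) {
      double* dst = A.colptr(c);
      const double* src = x.begin() + i + (size_t)n * xr * c;
      for (int r = 0; r < xr; ++r) dst[r] = src[(size_t)n * r];
    }
    for (int c = 0; c < yc; ++c) {
      double* dst = Bm.colptr(c);
      const double* src = y.begin() + i + (size_t)n * yr * c;
      for (int r = 0; r < yr; ++r) dst[r] = src[(size_t)n * r];
    }
    if (!transa && !transb) Cm = A * Bm;
    else if (transa && !transb) Cm = A.t() * Bm;
    else if (!transa && transb) Cm = A * Bm.t();
    else Cm = A.t() * Bm.t();
    for (int c = 0; c < p; ++c) {
      const double* src = Cm.colptr(c);
      double* dst = out.begin() + i + (size_t)n * m * c;
      for (int r = 0; r < m; ++r) dst[(size_t)n * r] = src[r];
    }
  }
  return out;
}
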