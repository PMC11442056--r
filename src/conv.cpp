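// Native 3D convolution kernels (2D is the depth-1 special case).
//
// Array layout follows R's column-major convention:
//   activations x : (D, H, W, C, N)   depth, height, width, channels, batch
//   weights     w : (kd, kh, kw, C, F)
// im2col rows are ordered (od, oh, ow) column-major so that a slab of the
// output array is exactly the (R x F) product matrix; the heavy lifting is a
// single BLAS GEMM per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvDims {
  int D, H, W, C, N;
  int kd, kh, kw, F;
  int sd, sh, sw;
  int pd, ph, pw;
  int Do, Ho, Wo;
};

ConvDims conv_dims(const NumericVector& x, const NumericVector& w,
                   const IntegerVector& stride, const IntegerVector& pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (xd.size() != 5) stop("input must be a 5-d array (D,H,W,C,N)");
  if (wd.size() != 5) stop("weights must be a 5-d array (kd,kh,kw,C,F)");
  ConvDims d;
  d.D = xd[0]; d.H = xd[1]; d.W = xd[2]; d.C = xd[3]; d.N = xd[4];
  d.kd = wd[0]; d.kh = wd[1]; d.kw = wd[2]; d.F = wd[4];
  if (wd[3] != d.C) stop("weight input channels do not match input");
  d.sd = stride[0]; d.sh = stride[1]; d.sw = stride[2];
  d.pd = pad[0]; d.ph = pad[1]; d.pw = pad[2];
  d.Do = (d.D + 2 * d.pd - d.kd) / d.sd + 1;
  d.Ho = (d.H + 2 * d.ph - d.kh) / d.sh + 1;
  d.Wo = (d.W + 2 * d.pw - d.kw) / d.sw + 1;
  if (d.Do < 1 || d.Ho < 1 || d.Wo < 1)
    stop("kernel larger than (padded) input");
  return d;
}

// Valid output range [lo, hi] so that o * stride - pad + koff lands in
// [0, extent).
inline void valid_range(int koff, int stride, int pad, int extent, int out,
                        int& lo, int& hi) {
  lo = 0;
  int start = -pad + koff;
  if (start < 0) lo = (-start + stride - 1) / stride;
  hi = out - 1;
  int last = (extent - 1 - start);
  if (last < 0) { hi = -1; return; }
  int hmax = last / stride;
  if (hmax < hi) hi = hmax;
}

// Gather one sample's patches into M (R x K); zero padding. Column-major
// loop order: each im2col column (one kernel offset x channel) is filled
// contiguously.
void im2col(const double* xs, const ConvDims& d, arma::mat& M) {
  M.zeros();
  int od_lo, od_hi, oh_lo, oh_hi, ow_lo, ow_hi;
  for (int c = 0; c < d.C; ++c) {
    const double* xc = xs + (size_t)d.D * d.H * d.W * c;
    for (int iw = 0; iw < d.kw; ++iw) {
      valid_range(iw, d.sw, d.pw, d.W, d.Wo, ow_lo, ow_hi);
      for (int ih = 0; ih < d.kh; ++ih) {
        valid_range(ih, d.sh, d.ph, d.H, d.Ho, oh_lo, oh_hi);
        for (int id = 0; id < d.kd; ++id) {
          valid_range(id, d.sd, d.pd, d.D, d.Do, od_lo, od_hi);
          const int k = id + d.kd * (ih + d.kh * (iw + d.kw * c));
          double* Mk = M.colptr(k);
          for (int ow = ow_lo; ow <= ow_hi; ++ow) {
            const int wI = ow * d.sw - d.pw + iw;
            for (int oh = oh_lo; oh <= oh_hi; ++oh) {
              const int hI = oh * d.sh - d.ph + ih;
              const double* src =
                  xc + (size_t)d.D * (hI + (size_t)d.H * wI) - d.pd + id;
              double* dst = Mk + od_lo + (size_t)d.Do * (oh + (size_t)d.Ho * ow);
              const double* s = src + (size_t)od_lo * d.sd;
              for (int od = od_lo; od <= od_hi; ++od) {
                *dst++ = *s;
                s += d.sd;
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add dM (R x K) back into one sample's gradient; same loop order.
void col2im(const arma::mat& dM, const ConvDims& d, double* dxs) {
  int od_lo, od_hi, oh_lo, oh_hi, ow_lo, ow_hi;
  for (int c = 0; c < d.C; ++c) {
    double* xc = dxs + (size_t)d.D * d.H * d.W * c;
    for (int iw = 0; iw < d.kw; ++iw) {
      valid_range(iw, d.sw, d.pw, d.W, d.Wo, ow_lo, ow_hi);
      for (int ih = 0; ih < d.kh; ++ih) {
        valid_range(ih, d.sh, d.ph, d.H, d.Ho, oh_lo, oh_hi);
        for (int id = 0; id < d.kd; ++id) {
          valid_range(id, d.sd, d.pd, d.D, d.Do, od_lo, od_hi);
          const int k = id + d.kd * (ih + d.kh * (iw + d.kw * c));
          const double* Mk = dM.colptr(k);
          for (int ow = ow_lo; ow <= ow_hi; ++ow) {
            const int wI = ow * d.sw - d.pw + iw;
            for (int oh = oh_lo; oh <= oh_hi; ++oh) {
              const int hI = oh * d.sh - d.ph + ih;
              double* dst =
                  xc + (size_t)d.D * (hI + (size_t)d.H * wI) - d.pd + id;
              const double* src =
                  Mk + od_lo + (size_t)d.Do * (oh + (size_t)d.Ho * ow);
              double* t = dst + (size_t)od_lo * d.sd;
              for (int od = od_lo; od <= od_hi; ++od) {
                *t += *src++;
                t += d.sd;
              }
            }
          }
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".conv_forward")]]
NumericVector conv_forward(NumericVector x, NumericVector w, NumericVector b,
                           IntegerVector stride, IntegerVector pad) {
  ConvDims d = conv_dims(x, w, stride, pad);
  const int R = d.Do * d.Ho * d.Wo;
  const int K = d.kd * d.kh * d.kw * d.C;
  if (b.size() != d.F) stop("bias length does not match output channels");

  NumericVector y((size_t)R * d.F * d.N);
  y.attr("dim") = IntegerVector::create(d.Do, d.Ho, d.Wo, d.F, d.N);

  arma::mat Wm(const_cast<double*>(w.begin()), K, d.F, false, true);
  arma::rowvec bias(const_cast<double*>(b.begin()), d.F, false, true);
  arma::mat M(R, K);
  const size_t xstep = (size_t)d.D * d.H * d.W * d.C;
  const size_t ystep = (size_t)R * d.F;
  for (int n = 0; n < d.N; ++n) {
    im2col(x.begin() + xstep * n, d, M);
    arma::mat Yn(y.begin() + ystep * n, R, d.F, false, true);
    Yn = M * Wm;
    Yn.each_row() += bias;
  }
  return y;
}

// [[Rcpp::export(name = ".conv_backward")]]
List conv_backward(NumericVector x, NumericVector w, NumericVector dy,
                   IntegerVector stride, IntegerVector pad) {
  ConvDims d = conv_dims(x, w, stride, pad);
  const int R = d.Do * d.Ho * d.Wo;
  const int K = d.kd * d.kh * d.kw * d.C;
  IntegerVector dyd = dy.attr("dim");
  if (dyd.size() != 5 || dyd[0] != d.Do || dyd[1] != d.Ho || dyd[2] != d.Wo ||
      dyd[3] != d.F || dyd[4] != d.N)
    stop("dy shape does not match forward output");

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(d.F);

  arma::mat Wm(const_cast<double*>(w.begin()), K, d.F, false, true);
  arma::mat dWm(dw.begin(), K, d.F, false, true);
  arma::rowvec dB(db.begin(), d.F, false, true);
  arma::mat M(R, K);
  const size_t xstep = (size_t)d.D * d.H * d.W * d.C;
  const size_t ystep = (size_t)R * d.F;
  for (int n = 0; n < d.N; ++n) {
    im2col(x.begin() + xstep * n, d, M);
    arma::mat Gn(const_cast<double*>(dy.begin()) + ystep * n, R, d.F, false,
                 true);
    dWm += M.t() * Gn;
    dB += arma::sum(Gn, 0);
    arma::mat dM = Gn * Wm.t();
    col2im(dM, d, dx.begin() + xstep * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
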