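// Compute kernels for 3D convolutional layers.
//
// Memory layout convention (column-major, matching R arrays):
//   feature tensors  : dim c(C, D, H, W, N)  -- channel fastest
//   conv weights     : matrix (Cin*kd*kh*kw) x Cout, row index
//                      cin + Cin*(od + kd*(oh + kh*ow))
// Convolutions carry no bias: every conv is followed by batch norm.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather one sample's patches into K ((Cin*kd*kh*kw) x nvox); column index
// od + Do*(oh + Ho*ow) so that Y = W' * K lands directly in (Cout,Do,Ho,Wo)
// column-major order.
static void im2col(const double* xs, int C, int D, int H, int W,
                   int kd, int kh, int kw, int stride, int pad,
                   int Do, int Ho, int Wo, arma::mat& K) {
  int col = 0;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      for (int od = 0; od < Do; ++od, ++col) {
        double* kc = K.colptr(col);
        const int d0 = od * stride - pad;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        int base = 0;
        for (int cw = 0; cw < kw; ++cw) {
          const int w = w0 + cw;
          for (int ch = 0; ch < kh; ++ch) {
            const int h = h0 + ch;
            for (int cd = 0; cd < kd; ++cd, base += C) {
              const int d = d0 + cd;
              if (d >= 0 && d < D && h >= 0 && h < H && w >= 0 && w < W) {
                const double* xp = xs +
                  (size_t)C * ((size_t)d + (size_t)D * ((size_t)h + (size_t)H * w));
                std::copy(xp, xp + C, kc + base);
              } else {
                std::fill(kc + base, kc + base + C, 0.0);
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add of dK back onto the input gradient (inverse of im2col).
static void col2im_add(double* dxs, int C, int D, int H, int W,
                       int kd, int kh, int kw, int stride, int pad,
                       int Do, int Ho, int Wo, const arma::mat& dK) {
  int col = 0;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      for (int od = 0; od < Do; ++od, ++col) {
        const double* kc = dK.colptr(col);
        const int d0 = od * stride - pad;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        int base = 0;
        for (int cw = 0; cw < kw; ++cw) {
          const int w = w0 + cw;
          for (int ch = 0; ch < kh; ++ch) {
            const int h = h0 + ch;
            for (int cd = 0; cd < kd; ++cd, base += C) {
              const int d = d0 + cd;
              if (d >= 0 && d < D && h >= 0 && h < H && w >= 0 && w < W) {
                double* dxp = dxs +
                  (size_t)C * ((size_t)d + (size_t)D * ((size_t)h + (size_t)H * w));
                for (int c = 0; c < C; ++c) dxp[c] += kc[base + c];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(const NumericVector& x, const IntegerVector& xdim,
                             const NumericMatrix& wmat, int kd, int kh, int kw,
                             int stride, int pad) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int Cout = wmat.ncol();
  if (wmat.nrow() != C * kd * kh * kw)
    stop("conv3d: weight rows %d do not match Cin*k^3 = %d", wmat.nrow(),
         C * kd * kh * kw);
  const int Do = out_size(D, kd, stride, pad);
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("conv3d: output has non-positive spatial size");
  const int nvox = Do * Ho * Wo;
  NumericVector y(Cout * (R_xlen_t)nvox * N);
  const arma::mat Wm(const_cast<double*>(wmat.begin()), wmat.nrow(), Cout,
                     false, true);
  arma::mat K(wmat.nrow(), nvox);
  const size_t xstep = (size_t)C * D * H * W;
  const size_t ystep = (size_t)Cout * nvox;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, C, D, H, W, kd, kh, kw, stride, pad,
           Do, Ho, Wo, K);
    arma::mat Ymap(y.begin() + n * ystep, Cout, nvox, false, true);
    Ymap = Wm.t() * K;
  }
  y.attr("dim") = IntegerVector::create(Cout, Do, Ho, Wo, N);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List cpp_conv3d_bwd(const NumericVector& x, const IntegerVector& xdim,
                    const NumericMatrix& wmat, const NumericVector& dy,
                    int kd, int kh, int kw, int stride, int pad,
                    bool need_dx) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int Cout = wmat.ncol();
  const int Do = out_size(D, kd, stride, pad);
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const int nvox = Do * Ho * Wo;
  if ((R_xlen_t)Cout * nvox * N != dy.size())
    stop("conv3d backward: dy size mismatch");
  const arma::mat Wm(const_cast<double*>(wmat.begin()), wmat.nrow(), Cout,
                     false, true);
  arma::mat dW(wmat.nrow(), Cout, arma::fill::zeros);
  NumericVector dx(need_dx ? x.size() : 0);
  arma::mat K(wmat.nrow(), nvox);
  const size_t xstep = (size_t)C * D * H * W;
  const size_t ystep = (size_t)Cout * nvox;
  for (int n = 0; n < N; ++n) {
    const arma::mat dYmap(const_cast<double*>(dy.begin()) + n * ystep,
                          Cout, nvox, false, true);
    im2col(x.begin() + n * xstep, C, D, H, W, kd, kh, kw, stride, pad,
           Do, Ho, Wo, K);
    dW += K * dYmap.t();
    if (need_dx) {
      arma::mat dK = Wm * dYmap;
      col2im_add(dx.begin() + n * xstep, C, D, H, W, kd, kh, kw, stride, pad,
                 Do, Ho, Wo, dK);
    }
  }
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(_["dw"] = wrap(dW), _["dx"] = dx);
}

// [[Rcpp::export(name = ".cpp_maxpool3d_fwd")]]
List cpp_maxpool3d_fwd(const NumericVector& x, const IntegerVector& xdim,
                       int k, int stride) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int Do = (D - k) / stride + 1;
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("maxpool3d: input spatial size smaller than kernel");
  const R_xlen_t ylen = (R_xlen_t)C * Do * Ho * Wo * N;
  NumericVector y(ylen);
  IntegerVector amax(ylen);  // 0-based linear index into x
  const size_t xstep = (size_t)C * D * H * W;
  R_xlen_t oi = 0;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * xstep;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od)
          for (int c = 0; c < C; ++c, ++oi) {
            double best = R_NegInf;
            size_t besti = 0;
            for (int cw = 0; cw < k; ++cw)
              for (int ch = 0; ch < k; ++ch)
                for (int cd = 0; cd < k; ++cd) {
                  const size_t d = od * stride + cd;
                  const size_t h = oh * stride + ch;
                  const size_t w = ow * stride + cw;
                  const size_t li = c + (size_t)C * (d + (size_t)D * (h + (size_t)H * w));
                  if (xs[li] > best) { best = xs[li]; besti = li; }
                }
            y[oi] = best;
            amax[oi] = (int)(besti + n * xstep);
          }
  }
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo, N);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".cpp_maxpool3d_bwd")]]
NumericVector cpp_maxpool3d_bwd(const NumericVector& dy,
                                const IntegerVector& amax, R_xlen_t xlen) {
  NumericVector dx(xlen);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[amax[i]] += dy[i];
  return dx;
}
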