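// Core dense 2-D convolution kernels used by the autodiff engine.
// Layout convention: images are [H, W, C, N] column-major (H fastest),
// weights are [kh, kw, Cin, Cout], so the im2col row index ki + kh*(kj + kw*c)
// lines up with the column-major flattening of one output filter.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col(const double* x, int H, int W, int C,
                          int kh, int kw, int stride, int pad,
                          int Ho, int Wo, arma::mat& col) {
  // col is (kh*kw*C) x (Ho*Wo), column q = ho + Ho*wo
  col.zeros();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            col(r, ho + Ho * wo) = x[hi + H * (wi + W * c)];
          }
        }
      }
    }
  }
}

static inline void col2im_acc(const arma::mat& col, int H, int W, int C,
                              int kh, int kw, int stride, int pad,
                              int Ho, int Wo, double* gx) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            gx[hi + H * (wi + W * c)] += col(r, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != C) stop("conv2d: channel mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output collapses to zero size");
  const int K = kh * kw * C;
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, Ho * Wo);
  arma::rowvec bias(const_cast<double*>(b.begin()), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat ym = col.t() * Wm;            // (Ho*Wo) x Cout
    ym.each_row() += bias;
    std::copy(ym.begin(), ym.end(), y.begin() + (size_t)n * Ho * Wo * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim"), dgy = gy.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  const int Ho = dgy[0], Wo = dgy[1];
  const int K = kh * kw * C;
  NumericVector gx(x.size());
  gx.attr("dim") = dx;
  arma::mat gW(K, Cout, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat gym(const_cast<double*>(gy.begin()) + (size_t)n * Ho * Wo * Cout,
                  Ho * Wo, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    gW += col * gym;                        // K x Cout
    gb += arma::sum(gym, 0);
    arma::mat gcol = Wm * gym.t();          // K x (Ho*Wo)
    col2im_acc(gcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
               gx.begin() + (size_t)n * H * W * C);
  }
  NumericVector gwv(gW.begin(), gW.end());
  gwv.attr("dim") = dw;
  NumericVector gbv(gb.begin(), gb.end());
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}
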