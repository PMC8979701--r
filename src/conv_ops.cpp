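// 3x3 same-padding convolution via im2col + BLAS GEMM, with the exact
// adjoint (col2im) for backprop. Activations travel in pixel-major matrix
// layout: a (P x C) matrix with row index p = h + H*w + H*W*n over pixels
// and batch members, so im2col reduces to contiguous column shifts
// (memcpy-speed) and batch-norm / ReLU / pooling stay as cheap vectorised
// matrix ops in R. Kernel column index k = (di+1) + 3*(dj+1) + 9*c with
// di/dj row/col offsets in {-1,0,1}; zero padding of width 1.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col: cols(p, k) = x(p shifted by (di, dj), c), zero outside the image
static void fill_cols_pm(const arma::mat& x, arma::mat& cols,
                         int H, int W, int N) {
  const int C = x.n_cols;
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = (di + 1) + 3 * (dj + 1) + 9 * c;
        double* dst = cols.colptr(k);
        const int h0 = (di < 0) ? 1 : 0;          // first valid output row
        const int len = H - std::abs(di);         // valid run length
        for (int n = 0; n < N; ++n) {
          const std::size_t poff = (std::size_t)HW * n;
          for (int w = 0; w < W; ++w) {
            double* d = dst + poff + (std::size_t)H * w;
            const int ws = w + dj;
            if (ws < 0 || ws >= W) {
              std::memset(d, 0, sizeof(double) * H);
            } else {
              const double* s = xc + poff + (std::size_t)H * ws + (h0 + di);
              if (h0) d[0] = 0.0;
              if (di > 0) d[H - 1] = 0.0;
              std::memcpy(d + h0, s, sizeof(double) * len);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv_pm_forward_cpp(NumericMatrix xmat, IntegerVector hwn,
                         NumericMatrix Wmat, NumericVector bias) {
  const int H = hwn[0], W = hwn[1], N = hwn[2];
  const int C = xmat.ncol();
  const int K = 9 * C;
  const int Co = Wmat.ncol();
  if (Wmat.nrow() != K) stop("weight matrix has %d rows, expected %d", Wmat.nrow(), K);
  if (bias.size() != Co) stop("bias length %d, expected %d", bias.size(), Co);
  const std::size_t P = (std::size_t)H * W * N;
  if ((std::size_t)xmat.nrow() != P) stop("input has %d rows, expected %d", xmat.nrow(), (int)P);

  const arma::mat x(xmat.begin(), P, C, false, true);
  arma::mat cols(P, K);
  fill_cols_pm(x, cols, H, W, N);
  const arma::mat Wm(Wmat.begin(), K, Co, false, true);
  arma::mat pre = cols * Wm;          // P x Co
  pre.each_row() += arma::rowvec(bias.begin(), Co);
  return List::create(_["pre"] = wrap(pre), _["cols"] = wrap(cols));
}

// [[Rcpp::export]]
List conv_pm_backward_cpp(NumericMatrix dmatR, IntegerVector hwn, int C,
                          NumericMatrix colsR, NumericMatrix Wmat) {
  const int H = hwn[0], W = hwn[1], N = hwn[2];
  const int K = 9 * C;
  const int Co = Wmat.ncol();
  const int HW = H * W;
  const std::size_t P = (std::size_t)HW * N;

  const arma::mat dmat(dmatR.begin(), P, Co, false, true);
  const arma::mat cols(colsR.begin(), P, K, false, true);
  const arma::mat Wm(Wmat.begin(), K, Co, false, true);

  arma::mat dW = cols.t() * dmat;     // K x Co
  arma::rowvec db = arma::sum(dmat, 0);
  arma::mat dcols = dmat * Wm.t();    // P x K

  // col2im: scatter-add the adjoint of fill_cols_pm
  arma::mat dx(P, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = dx.colptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = (di + 1) + 3 * (dj + 1) + 9 * c;
        const double* src = dcols.colptr(k);
        const int h0 = (di < 0) ? 1 : 0;
        const int len = H - std::abs(di);
        for (int n = 0; n < N; ++n) {
          const std::size_t poff = (std::size_t)HW * n;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dj;
            if (ws < 0 || ws >= W) continue;
            const double* s = src + poff + (std::size_t)H * w + h0;
            double* d = xc + poff + (std::size_t)H * ws + (h0 + di);
            for (int h = 0; h < len; ++h) d[h] += s[h];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = wrap(dx), _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Batch-norm forward/backward and 2x2 average pooling on pixel-major
// (P x C) activation matrices; Armadillo each_row ops avoid the cost of
// R-level broadcasting on large matrices.

// [[Rcpp::export]]
List bn_fwd_cpp(NumericMatrix preR, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, bool train,
                double eps) {
  const int P = preR.nrow(), C = preR.ncol();
  const arma::mat pre(preR.begin(), P, C, false, true);
  const arma::rowvec g(gamma.begin(), C), b(beta.begin(), C);
  arma::rowvec mu, v, inv;
  arma::mat xhat;
  if (train) {
    mu = arma::mean(pre, 0);
    xhat = pre.each_row() - mu;
    v = arma::mean(arma::square(xhat), 0);
    inv = 1.0 / arma::sqrt(v + eps);
    xhat.each_row() %= inv;
  } else {
    mu = arma::rowvec(rmean.begin(), C);
    v = arma::rowvec(rvar.begin(), C);
    inv = 1.0 / arma::sqrt(v + eps);
    xhat = (pre.each_row() - mu).each_row() % inv;
  }
  arma::mat out = xhat.each_row() % g;
  out.each_row() += b;
  return List::create(_["out"] = wrap(out), _["xhat"] = wrap(xhat),
                      _["inv"] = NumericVector(inv.begin(), inv.end()),
                      _["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["v"] = NumericVector(v.begin(), v.end()));
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericMatrix doutR, NumericMatrix xhatR,
                NumericVector invR, NumericVector gamma) {
  const int P = doutR.nrow(), C = doutR.ncol();
  const arma::mat dout(doutR.begin(), P, C, false, true);
  const arma::mat xhat(xhatR.begin(), P, C, false, true);
  const arma::rowvec inv(invR.begin(), C), g(gamma.begin(), C);
  arma::rowvec dgamma = arma::sum(dout % xhat, 0);
  arma::rowvec dbeta = arma::sum(dout, 0);
  arma::mat dxh = dout.each_row() % g;
  arma::rowvec m1 = arma::mean(dxh, 0);
  arma::rowvec m2 = arma::mean(dxh % xhat, 0);
  arma::mat dx = dxh.each_row() - m1;
  dx -= xhat.each_row() % m2;
  dx.each_row() %= inv;
  return List::create(_["dx"] = wrap(dx),
                      _["dgamma"] = NumericVector(dgamma.begin(), dgamma.end()),
                      _["dbeta"] = NumericVector(dbeta.begin(), dbeta.end()));
}

// [[Rcpp::export]]
NumericMatrix pool2_fwd_cpp(NumericMatrix actR, IntegerVector hwn) {
  const int H = hwn[0], W = hwn[1], N = hwn[2];
  const int C = actR.ncol(), HW = H * W;
  const int Ho = H / 2, Wo = W / 2, HWo = Ho * Wo;
  NumericMatrix out((std::size_t)HWo * N, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &actR(0, c);
    double* dst = &out(0, c);
    for (int n = 0; n < N; ++n) {
      const double* s = src + (std::size_t)HW * n;
      double* d = dst + (std::size_t)HWo * n;
      for (int wo = 0; wo < Wo; ++wo) {
        const double* s0 = s + (std::size_t)H * 2 * wo;
        const double* s1 = s0 + H;
        for (int ho = 0; ho < Ho; ++ho)
          d[ho + (std::size_t)Ho * wo] =
            (s0[2 * ho] + s0[2 * ho + 1] + s1[2 * ho] + s1[2 * ho + 1]) * 0.25;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix pool2_bwd_cpp(NumericMatrix doutR, IntegerVector hwn) {
  const int H = hwn[0], W = hwn[1], N = hwn[2];
  const int C = doutR.ncol(), HW = H * W;
  const int Ho = H / 2, Wo = W / 2, HWo = Ho * Wo;
  NumericMatrix dx((std::size_t)HW * N, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &doutR(0, c);
    double* dst = &dx(0, c);
    for (int n = 0; n < N; ++n) {
      const double* s = src + (std::size_t)HWo * n;
      double* d = dst + (std::size_t)HW * n;
      for (int wo = 0; wo < Wo; ++wo) {
        double* d0 = d + (std::size_t)H * 2 * wo;
        double* d1 = d0 + H;
        for (int ho = 0; ho < Ho; ++ho) {
          const double gv = s[ho + (std::size_t)Ho * wo] * 0.25;
          d0[2 * ho] = gv; d0[2 * ho + 1] = gv;
          d1[2 * ho] = gv; d1[2 * ho + 1] = gv;
        }
      }
    }
  }
  return dx;
}
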