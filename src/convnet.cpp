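// Minimal convolutional-network kernels used by the R-level layer framework.
// Tensors are R arrays in column-major order with dim = c(H, W, C, N):
// spatial rows (y), spatial cols (x), channels, batch. Weights for a
// convolution are dim = c(K, K, C_in/groups, C_out). All convolutions are
// cross-correlations (the deep-learning convention).

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

static inline void dims4(const NumericVector &x, int &d0, int &d1, int &d2,
                         int &d3) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  d0 = d[0]; d1 = d[1]; d2 = d[2]; d3 = d[3];
}

// Gather the im2col matrix for one sample and one channel group.
// M has dim (K*K*Cg) x (oH*oW); row index = ki + K*kj + K*K*c.
static void im2col(const double *xc_base, int H, int W, int Cg, size_t chan_stride,
                   int K, int stride, int pad, int oH, int oW, arma::mat &M) {
  M.zeros();
  for (int c = 0; c < Cg; ++c) {
    const double *xc = xc_base + chan_stride * c;
    for (int oj = 0; oj < oW; ++oj) {
      const int wi0 = oj * stride - pad;
      for (int oi = 0; oi < oH; ++oi) {
        const int hi0 = oi * stride - pad;
        const int col = oi + oH * oj;
        for (int kj = 0; kj < K; ++kj) {
          const int wi = wi0 + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int hi = hi0 + ki;
            if (hi < 0 || hi >= H) continue;
            M(ki + K * kj + K * K * c, col) = xc[hi + (size_t)H * wi];
          }
        }
      }
    }
  }
}

// Scatter-add of a column matrix back into the input gradient (col2im).
static void col2im(double *gxc_base, int H, int W, int Cg, size_t chan_stride,
                   int K, int stride, int pad, int oH, int oW,
                   const arma::mat &M) {
  for (int c = 0; c < Cg; ++c) {
    double *gxc = gxc_base + chan_stride * c;
    for (int oj = 0; oj < oW; ++oj) {
      const int wi0 = oj * stride - pad;
      for (int oi = 0; oi < oH; ++oi) {
        const int hi0 = oi * stride - pad;
        const int col = oi + oH * oj;
        for (int kj = 0; kj < K; ++kj) {
          const int wi = wi0 + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int hi = hi0 + ki;
            if (hi < 0 || hi >= H) continue;
            gxc[hi + (size_t)H * wi] += M(ki + K * kj + K * K * c, col);
          }
        }
      }
    }
  }
}

// Flatten the weights of one group into a (OCg x K*K*Cg) matrix matching the
// im2col row ordering.
static arma::mat weight_mat(const double *wp, int K, int Cg, int OCg, int g) {
  const int rows = K * K * Cg;
  arma::mat Wm(OCg, rows);
  for (int oc = 0; oc < OCg; ++oc)
    for (int c = 0; c < Cg; ++c)
      for (int kj = 0; kj < K; ++kj)
        for (int ki = 0; ki < K; ++ki)
          Wm(oc, ki + K * kj + K * K * c) =
              wp[ki + (size_t)K * (kj + (size_t)K * (c + (size_t)Cg * ((size_t)g * OCg + oc)))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int groups) {
  int H, W, C, N, K, K2, Cg, OC;
  dims4(x, H, W, C, N);
  dims4(w, K, K2, Cg, OC);
  if (K != K2) stop("non-square kernel");
  if (C != Cg * groups) stop("channel/group mismatch");
  if (OC % groups != 0) stop("out-channels not divisible by groups");
  const int oH = (H + 2 * pad - K) / stride + 1;
  const int oW = (W + 2 * pad - K) / stride + 1;
  if (oH < 1 || oW < 1) stop("input smaller than kernel");
  const int OCg = OC / groups;
  const int rows = K * K * Cg;
  NumericVector out((size_t)oH * oW * OC * N);
  out.attr("dim") = IntegerVector::create(oH, oW, OC, N);

  std::vector<arma::mat> Wg(groups);
  for (int g = 0; g < groups; ++g) Wg[g] = weight_mat(w.begin(), K, Cg, OCg, g);

  arma::mat M(rows, (size_t)oH * oW);
  const double *xp = x.begin();
  double *op = out.begin();
  const size_t plane = (size_t)H * W, oplane = (size_t)oH * oW;
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double *xc0 = xp + ((size_t)n * C + (size_t)g * Cg) * plane;
      im2col(xc0, H, W, Cg, plane, K, stride, pad, oH, oW, M);
      arma::mat Y = Wg[g] * M; // OCg x (oH*oW)
      for (int oc = 0; oc < OCg; ++oc) {
        const int occ = g * OCg + oc;
        const double bb = b[occ];
        double *od = op + ((size_t)n * OC + occ) * oplane;
        for (size_t col = 0; col < oplane; ++col) od[col] = Y(oc, col) + bb;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int groups) {
  int H, W, C, N, K, K2, Cg, OC, oH, oW, OC2, N2;
  dims4(x, H, W, C, N);
  dims4(w, K, K2, Cg, OC);
  dims4(gy, oH, oW, OC2, N2);
  if (OC2 != OC || N2 != N) stop("gradient shape mismatch");
  const int OCg = OC / groups;
  const int rows = K * K * Cg;

  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(OC);

  std::vector<arma::mat> Wg(groups), gWm(groups);
  for (int g = 0; g < groups; ++g) {
    Wg[g] = weight_mat(w.begin(), K, Cg, OCg, g);
    gWm[g] = arma::mat(OCg, rows, arma::fill::zeros);
  }

  arma::mat M(rows, (size_t)oH * oW), G(OCg, (size_t)oH * oW);
  const double *xp = x.begin(), *gp = gy.begin();
  double *gxp = gx.begin();
  const size_t plane = (size_t)H * W, oplane = (size_t)oH * oW;
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double *xc0 = xp + ((size_t)n * C + (size_t)g * Cg) * plane;
      im2col(xc0, H, W, Cg, plane, K, stride, pad, oH, oW, M);
      for (int oc = 0; oc < OCg; ++oc) {
        const int occ = g * OCg + oc;
        const double *gd = gp + ((size_t)n * OC + occ) * oplane;
        double s = 0.0;
        for (size_t col = 0; col < oplane; ++col) {
          G(oc, col) = gd[col];
          s += gd[col];
        }
        gb[occ] += s;
      }
      gWm[g] += G * M.t();
      arma::mat GX = Wg[g].t() * G; // rows x oplane
      col2im(gxp + ((size_t)n * C + (size_t)g * Cg) * plane, H, W, Cg, plane,
             K, stride, pad, oH, oW, GX);
    }
  }
  double *gwp = gw.begin();
  for (int g = 0; g < groups; ++g)
    for (int oc = 0; oc < OCg; ++oc)
      for (int c = 0; c < Cg; ++c)
        for (int kj = 0; kj < K; ++kj)
          for (int ki = 0; ki < K; ++ki)
            gwp[ki + (size_t)K * (kj + (size_t)K * (c + (size_t)Cg * ((size_t)g * OCg + oc)))] =
                gWm[g](oc, ki + K * kj + K * K * c);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling with stride 2; trailing odd row/column dropped (floor).
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const int oH = H / 2, oW = W / 2;
  if (oH < 1 || oW < 1) stop("input too small to pool");
  NumericVector out((size_t)oH * oW * C * N);
  out.attr("dim") = IntegerVector::create(oH, oW, C, N);
  IntegerVector arg(out.size()); // 0-based linear index into x
  const double *xp = x.begin();
  double *op = out.begin();
  int *ap = arg.begin();
  const size_t plane = (size_t)H * W, oplane = (size_t)oH * oW;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t xoff = ((size_t)n * C + c) * plane;
      const size_t ooff = ((size_t)n * C + c) * oplane;
      for (int oj = 0; oj < oW; ++oj)
        for (int oi = 0; oi < oH; ++oi) {
          size_t best = xoff + (size_t)(2 * oi) + (size_t)H * (2 * oj);
          double bv = xp[best];
          const int di[3] = {1, 0, 1};
          const int dj[3] = {0, 1, 1};
          for (int t = 0; t < 3; ++t) {
            size_t idx = xoff + (size_t)(2 * oi + di[t]) + (size_t)H * (2 * oj + dj[t]);
            if (xp[idx] > bv) { bv = xp[idx]; best = idx; }
          }
          op[ooff + oi + (size_t)oH * oj] = bv;
          ap[ooff + oi + (size_t)oH * oj] = (int)best;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(IntegerVector argmax, NumericVector gy,
                               IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  double *gxp = gx.begin();
  const double *gp = gy.begin();
  const int *ap = argmax.begin();
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[ap[i]] += gp[i];
  return gx;
}
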