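// Low-level tensor operators for the detection stack.
//
// Layout conventions (column-major R arrays):
//   feature map  x : dim c(N, C, H, W)      element (n,c,h,w) -> n + N*(c + C*(h + H*w))
//   conv weight  w : dim c(Cout, Cin/g, kh, kw)
//   receptive-field tensor: dim c(N, C*k*k, Ho, Wo), channel u = c + C*(i + k*j)
//   CARAFE kernel field   : dim c(N, kup*kup, sH, sW), tap t = (di+r) + kup*(dj+r)
//
// All backward passes are hand-derived; gradient correctness is asserted against
// finite differences in the test suite.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int H, int k, int s, int p, int d) {
  return (H + 2 * p - d * (k - 1) - 1) / s + 1;
}

static inline R_xlen_t IX(int n, int c, int h, int w, int N, int C, int H) {
  return n + (R_xlen_t)N * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
}

static IntegerVector dims_of(const NumericVector& x) {
  return as<IntegerVector>(x.attr("dim"));
}

// im2col for one (sample, group): rows = Cg*kh*kw, cols = Ho*Wo
static void im2col(const double* x, int n, int N, int C, int H, int W,
                   int c0, int Cg, int kh, int kw, int s, int p, int d,
                   int Ho, int Wo, arma::mat& col) {
  for (int j = 0; j < kw; ++j) {
    for (int i = 0; i < kh; ++i) {
      for (int ci = 0; ci < Cg; ++ci) {
        int r = ci + Cg * (i + kh * j);
        int c = c0 + ci;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + j * d;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + i * d;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = x[IX(n, c, hi, wi, N, C, H)];
            col(r, ho + Ho * wo) = v;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, double* gx, int n, int N, int C, int H,
                   int W, int c0, int Cg, int kh, int kw, int s, int p, int d,
                   int Ho, int Wo) {
  for (int j = 0; j < kw; ++j) {
    for (int i = 0; i < kh; ++i) {
      for (int ci = 0; ci < Cg; ++ci) {
        int r = ci + Cg * (i + kh * j);
        int c = c0 + ci;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + j * d;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + i * d;
            if (hi < 0 || hi >= H) continue;
            gx[IX(n, c, hi, wi, N, C, H)] += col(r, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv2d_fw2(NumericVector x, NumericVector w, NumericVector b,
                    int stride, int pad, int dilation, int groups,
                    bool keep_col) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], Cg = wd[1], kh = wd[2], kw = wd[3];
  if (C != Cg * groups) stop("conv2d: channel/group mismatch");
  int Coutg = Cout / groups;
  int Ho = out_size(H, kh, stride, pad, dilation);
  int Wo = out_size(W, kw, stride, pad, dilation);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size < 1");
  NumericVector y((R_xlen_t)N * Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, Cout, Ho, Wo);
  bool has_b = b.size() > 0;
  int Rr = Cg * kh * kw, M = Ho * Wo;
  // col matrices for every group, optionally returned for reuse in backward
  List cols(keep_col ? groups : 0);
  arma::mat col(Rr, (R_xlen_t)N * M);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm(Coutg, Rr);
    for (int r = 0; r < Rr; ++r)
      for (int o = 0; o < Coutg; ++o)
        Wm(o, r) = w[(g * Coutg + o) + (R_xlen_t)Cout * r];
    for (int n = 0; n < N; ++n) {
      arma::mat sub(col.colptr((R_xlen_t)n * M), Rr, M, false, true);
      im2col(x.begin(), n, N, C, H, W, g * Cg, Cg, kh, kw, stride, pad, dilation,
             Ho, Wo, sub);
    }
    arma::mat out = Wm * col;  // Coutg x N*M
    for (int n = 0; n < N; ++n)
      for (int m = 0; m < M; ++m) {
        int ho = m % Ho, wo = m / Ho;
        for (int o = 0; o < Coutg; ++o) {
          int oc = g * Coutg + o;
          double v = out(o, (R_xlen_t)n * M + m);
          if (has_b) v += b[oc];
          y[IX(n, oc, ho, wo, N, Cout, Ho)] = v;
        }
      }
    if (keep_col)
      cols[g] = NumericVector(col.begin(), col.end());
  }
  return List::create(_["y"] = y, _["cols"] = cols);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, int dilation, int groups) {
  List r = cpp_conv2d_fw2(x, w, b, stride, pad, dilation, groups, false);
  return r["y"];
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xdim, NumericVector w,
                   NumericVector gy, int stride, int pad, int dilation,
                   int groups, bool need_gx, bool has_bias,
                   Nullable<List> cached_cols) {
  IntegerVector xd = xdim, wd = dims_of(w), yd = dims_of(gy);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], Cg = wd[1], kh = wd[2], kw = wd[3];
  int Ho = yd[2], Wo = yd[3];
  int Coutg = Cout / groups;
  int Rr = Cg * kh * kw, M = Ho * Wo;
  NumericVector gx(need_gx ? (R_xlen_t)N * C * H * W : 0);
  if (need_gx)
    gx.attr("dim") = IntegerVector::create(N, C, H, W);
  NumericVector gw((R_xlen_t)w.size());
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Cout : 0);
  bool have_cols = cached_cols.isNotNull();
  List ccols;
  if (have_cols) ccols = cached_cols.get();
  arma::mat col(Rr, (R_xlen_t)N * M), Gy(Coutg, (R_xlen_t)N * M);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm(Coutg, Rr);
    for (int r = 0; r < Rr; ++r)
      for (int o = 0; o < Coutg; ++o)
        Wm(o, r) = w[(g * Coutg + o) + (R_xlen_t)Cout * r];
    if (have_cols) {
      NumericVector cv = ccols[g];
      std::copy(cv.begin(), cv.end(), col.memptr());
    }
    for (int n = 0; n < N; ++n) {
      for (int m = 0; m < M; ++m) {
        int ho = m % Ho, wo = m / Ho;
        for (int o = 0; o < Coutg; ++o)
          Gy(o, (R_xlen_t)n * M + m) = gy[IX(n, g * Coutg + o, ho, wo, N, Cout, Ho)];
      }
      if (!have_cols) {
        arma::mat sub(col.colptr((R_xlen_t)n * M), Rr, M, false, true);
        im2col(x.begin(), n, N, C, H, W, g * Cg, Cg, kh, kw, stride, pad, dilation,
               Ho, Wo, sub);
      }
    }
    arma::mat Gw = Gy * col.t();
    if (need_gx) {
      arma::mat gcol = Wm.t() * Gy;  // Rr x N*M
      for (int n = 0; n < N; ++n) {
        arma::mat sub(gcol.colptr((R_xlen_t)n * M), Rr, M, false, true);
        col2im(sub, gx.begin(), n, N, C, H, W, g * Cg, Cg, kh, kw, stride, pad,
               dilation, Ho, Wo);
      }
    }
    if (has_bias)
      for (int o = 0; o < Coutg; ++o)
        gb[g * Coutg + o] = arma::accu(Gy.row(o));
    for (int r = 0; r < Rr; ++r)
      for (int o = 0; o < Coutg; ++o)
        gw[(g * Coutg + o) + (R_xlen_t)Cout * r] = Gw(o, r);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = dims_of(x);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Ho = out_size(H, k, stride, pad, 1);
  int Wo = out_size(W, k, stride, pad, 1);
  NumericVector y((R_xlen_t)N * C * Ho * Wo);
  IntegerVector idx((R_xlen_t)N * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  idx.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          R_xlen_t bi = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              R_xlen_t xi = IX(n, c, hi, wi, N, C, H);
              if (x[xi] > best) { best = x[xi]; bi = xi; }
            }
          }
          R_xlen_t yi = IX(n, c, ho, wo, N, C, Ho);
          y[yi] = best;
          idx[yi] = (int)bi;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector gy,
                             IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (idx[i] >= 0) gx[idx[i]] += gy[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upnn_fw(NumericVector x, int s) {
  IntegerVector xd = dims_of(x);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Ho = H * s, Wo = W * s;
  NumericVector y((R_xlen_t)N * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      int hi = ho / s, wi = wo / s;
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          y[IX(n, c, ho, wo, N, C, Ho)] = x[IX(n, c, hi, wi, N, C, H)];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upnn_bw(NumericVector gy, int s) {
  IntegerVector yd = dims_of(gy);
  int N = yd[0], C = yd[1], Ho = yd[2], Wo = yd[3];
  int H = Ho / s, W = Wo / s;
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      int hi = ho / s, wi = wo / s;
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          gx[IX(n, c, hi, wi, N, C, H)] += gy[IX(n, c, ho, wo, N, C, Ho)];
    }
  return gx;
}

// receptive-field expansion: [N,C,H,W] -> [N, C*k*k, Ho, Wo]
// [[Rcpp::export]]
NumericVector cpp_rf_expand(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = dims_of(x);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Ho = out_size(H, k, stride, pad, 1);
  int Wo = out_size(W, k, stride, pad, 1);
  if (Ho < 1 || Wo < 1) stop("rf_expand: output size < 1");
  int Cu = C * k * k;
  NumericVector y((R_xlen_t)N * Cu * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, Cu, Ho, Wo);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < k; ++i)
      for (int c = 0; c < C; ++c) {
        int u = c + C * (i + k * j);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            bool in = hi >= 0 && hi < H && wi >= 0 && wi < W;
            for (int n = 0; n < N; ++n)
              y[IX(n, u, ho, wo, N, Cu, Ho)] =
                in ? x[IX(n, c, hi, wi, N, C, H)] : 0.0;
          }
        }
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_rf_expand_bw(NumericVector gy, IntegerVector xdim, int k,
                               int stride, int pad) {
  int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  IntegerVector yd = dims_of(gy);
  int Cu = yd[1], Ho = yd[2], Wo = yd[3];
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = xdim;
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < k; ++i)
      for (int c = 0; c < C; ++c) {
        int u = c + C * (i + k * j);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            for (int n = 0; n < N; ++n)
              gx[IX(n, c, hi, wi, N, C, H)] += gy[IX(n, u, ho, wo, N, Cu, Ho)];
          }
        }
      }
  return gx;
}

// tile rearrangement for grouped-conv output: [N, C*k2, H, W] -> [N, C, kH, kW]
// input channel u = c*k2 + t with t = i + k*j
// [[Rcpp::export]]
NumericVector cpp_tile_rearrange(NumericVector x, int k) {
  IntegerVector xd = dims_of(x);
  int N = xd[0], Cu = xd[1], H = xd[2], W = xd[3];
  int k2 = k * k, C = Cu / k2;
  int Ho = k * H, Wo = k * W;
  NumericVector y((R_xlen_t)N * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < k; ++i)
          for (int c = 0; c < C; ++c) {
            int u = c * k2 + (i + k * j);
            for (int n = 0; n < N; ++n)
              y[IX(n, c, k * h + i, k * w + j, N, C, Ho)] =
                x[IX(n, u, h, w, N, Cu, H)];
          }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_tile_rearrange_bw(NumericVector gy, int k) {
  IntegerVector yd = dims_of(gy);
  int N = yd[0], C = yd[1], Ho = yd[2], Wo = yd[3];
  int H = Ho / k, W = Wo / k, k2 = k * k, Cu = C * k2;
  NumericVector gx((R_xlen_t)N * Cu * H * W);
  gx.attr("dim") = IntegerVector::create(N, Cu, H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < k; ++i)
          for (int c = 0; c < C; ++c) {
            int u = c * k2 + (i + k * j);
            for (int n = 0; n < N; ++n)
              gx[IX(n, u, h, w, N, Cu, H)] =
                gy[IX(n, c, k * h + i, k * w + j, N, C, Ho)];
          }
  return gx;
}

// CARAFE reassembly: y[n,c,ho,wo] = sum_t kern[n,t,ho,wo] * x[n,c,hc+di,wc+dj]
// [[Rcpp::export]]
NumericVector cpp_carafe_fw(NumericVector x, NumericVector kern, int sigma,
                            int kup) {
  IntegerVector xd = dims_of(x), kd = dims_of(kern);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int K2 = kd[1], Ho = kd[2], Wo = kd[3];
  if (K2 != kup * kup || Ho != sigma * H || Wo != sigma * W)
    stop("carafe: kernel field inconsistent with input/sigma/kup");
  int r = (kup - 1) / 2;
  NumericVector y((R_xlen_t)N * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    int wc = wo / sigma;
    for (int ho = 0; ho < Ho; ++ho) {
      int hc = ho / sigma;
      for (int dj = -r; dj <= r; ++dj) {
        int wi = wc + dj;
        if (wi < 0 || wi >= W) continue;
        for (int di = -r; di <= r; ++di) {
          int hi = hc + di;
          if (hi < 0 || hi >= H) continue;
          int t = (di + r) + kup * (dj + r);
          for (int n = 0; n < N; ++n) {
            double wgt = kern[IX(n, t, ho, wo, N, K2, Ho)];
            if (wgt == 0.0) continue;
            for (int c = 0; c < C; ++c)
              y[IX(n, c, ho, wo, N, C, Ho)] +=
                wgt * x[IX(n, c, hi, wi, N, C, H)];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_carafe_bw(NumericVector x, NumericVector kern, NumericVector gy,
                   int sigma, int kup) {
  IntegerVector xd = dims_of(x), kd = dims_of(kern);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int K2 = kd[1], Ho = kd[2], Wo = kd[3];
  int r = (kup - 1) / 2;
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = xd;
  NumericVector gk((R_xlen_t)N * K2 * Ho * Wo);
  gk.attr("dim") = kd;
  for (int wo = 0; wo < Wo; ++wo) {
    int wc = wo / sigma;
    for (int ho = 0; ho < Ho; ++ho) {
      int hc = ho / sigma;
      for (int dj = -r; dj <= r; ++dj) {
        int wi = wc + dj;
        if (wi < 0 || wi >= W) continue;
        for (int di = -r; di <= r; ++di) {
          int hi = hc + di;
          if (hi < 0 || hi >= H) continue;
          int t = (di + r) + kup * (dj + r);
          for (int n = 0; n < N; ++n) {
            double wgt = kern[IX(n, t, ho, wo, N, K2, Ho)];
            double acc = 0.0;
            for (int c = 0; c < C; ++c) {
              double g = gy[IX(n, c, ho, wo, N, C, Ho)];
              gx[IX(n, c, hi, wi, N, C, H)] += wgt * g;
              acc += g * x[IX(n, c, hi, wi, N, C, H)];
            }
            gk[IX(n, t, ho, wo, N, K2, Ho)] += acc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gk"] = gk);
}

// affine-free batch normalisation over (N,H,W) per channel
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, NumericVector rmean, NumericVector rvar,
               double eps, double momentum, bool train) {
  IntegerVector xd = dims_of(x);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  R_xlen_t M = (R_xlen_t)N * H * W;
  NumericVector y((R_xlen_t)N * C * H * W);
  y.attr("dim") = xd;
  NumericVector mu(C), invstd(C), nrm(C), nrv(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          for (int n = 0; n < N; ++n) {
            double v = x[IX(n, c, h, w, N, C, H)];
            s += v; s2 += v * v;
          }
      double m = s / M;
      double var = s2 / M - m * m;
      if (var < 0) var = 0;
      mu[c] = m;
      invstd[c] = 1.0 / std::sqrt(var + eps);
      nrm[c] = (1 - momentum) * rmean[c] + momentum * m;
      double ub = M > 1 ? var * M / (M - 1.0) : var;
      nrv[c] = (1 - momentum) * rvar[c] + momentum * ub;
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rmean[c];
      invstd[c] = 1.0 / std::sqrt(rvar[c] + eps);
      nrm[c] = rmean[c];
      nrv[c] = rvar[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    double m = mu[c], is = invstd[c];
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int n = 0; n < N; ++n) {
          R_xlen_t i = IX(n, c, h, w, N, C, H);
          y[i] = (x[i] - m) * is;
        }
  }
  return List::create(_["y"] = y, _["invstd"] = invstd, _["rmean"] = nrm,
                      _["rvar"] = nrv);
}

// [[Rcpp::export]]
NumericVector cpp_bn_bw(NumericVector gy, NumericVector xhat,
                        NumericVector invstd, bool train) {
  IntegerVector xd = dims_of(gy);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  R_xlen_t M = (R_xlen_t)N * H * W;
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double is = invstd[c];
    if (train) {
      double sg = 0.0, sgx = 0.0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          for (int n = 0; n < N; ++n) {
            R_xlen_t i = IX(n, c, h, w, N, C, H);
            sg += gy[i];
            sgx += gy[i] * xhat[i];
          }
      double mg = sg / M, mgx = sgx / M;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          for (int n = 0; n < N; ++n) {
            R_xlen_t i = IX(n, c, h, w, N, C, H);
            gx[i] = is * (gy[i] - mg - xhat[i] * mgx);
          }
    } else {
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          for (int n = 0; n < N; ++n) {
            R_xlen_t i = IX(n, c, h, w, N, C, H);
            gx[i] = is * gy[i];
          }
    }
  }
  return gx;
}

// directional mean pooling: x [N,C,H,W] -> xh [N,C,H,1], xwt [N,C,W,1]
// [[Rcpp::export]]
List cpp_dirpool_fw(NumericVector x) {
  IntegerVector xd = dims_of(x);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector xh((R_xlen_t)N * C * H), xwt((R_xlen_t)N * C * W);
  xh.attr("dim") = IntegerVector::create(N, C, H, 1);
  xwt.attr("dim") = IntegerVector::create(N, C, W, 1);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double v = x[IX(n, c, h, w, N, C, H)];
          xh[n + (R_xlen_t)N * (c + (R_xlen_t)C * h)] += v / W;
          xwt[n + (R_xlen_t)N * (c + (R_xlen_t)C * w)] += v / H;
        }
  return List::create(_["xh"] = xh, _["xwt"] = xwt);
}

// [[Rcpp::export]]
NumericVector cpp_dirpool_bw(NumericVector gxh, NumericVector gxwt,
                             IntegerVector xdim) {
  int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = xdim;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          gx[IX(n, c, h, w, N, C, H)] =
            gxh[n + (R_xlen_t)N * (c + (R_xlen_t)C * h)] / W +
            gxwt[n + (R_xlen_t)N * (c + (R_xlen_t)C * w)] / H;
  return gx;
}

// broadcast attention multiply: y = e * ah (over W) * aw (over H)
// e [N,C,H,W], ah [N,C,H,1], aw [N,C,1,W] (stored as [N,C,W,1] transposed)
// [[Rcpp::export]]
NumericVector cpp_attnmul_fw(NumericVector e, NumericVector ah,
                             NumericVector awt) {
  IntegerVector ed = dims_of(e);
  int N = ed[0], C = ed[1], H = ed[2], W = ed[3];
  NumericVector y((R_xlen_t)e.size());
  y.attr("dim") = ed;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          y[IX(n, c, h, w, N, C, H)] = e[IX(n, c, h, w, N, C, H)] *
            ah[n + (R_xlen_t)N * (c + (R_xlen_t)C * h)] *
            awt[n + (R_xlen_t)N * (c + (R_xlen_t)C * w)];
  return y;
}

// [[Rcpp::export]]
List cpp_attnmul_bw(NumericVector e, NumericVector ah, NumericVector awt,
                    NumericVector gy) {
  IntegerVector ed = dims_of(e);
  int N = ed[0], C = ed[1], H = ed[2], W = ed[3];
  NumericVector ge((R_xlen_t)e.size()), gah((R_xlen_t)N * C * H),
    gawt((R_xlen_t)N * C * W);
  ge.attr("dim") = ed;
  gah.attr("dim") = IntegerVector::create(N, C, H, 1);
  gawt.attr("dim") = IntegerVector::create(N, C, W, 1);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          R_xlen_t ie = IX(n, c, h, w, N, C, H);
          R_xlen_t ih = n + (R_xlen_t)N * (c + (R_xlen_t)C * h);
          R_xlen_t iw = n + (R_xlen_t)N * (c + (R_xlen_t)C * w);
          double g = gy[ie];
          ge[ie] = g * ah[ih] * awt[iw];
          gah[ih] += g * e[ie] * awt[iw];
          gawt[iw] += g * e[ie] * ah[ih];
        }
  return List::create(_["ge"] = ge, _["gah"] = gah, _["gawt"] = gawt);
}

static inline double act_apply(double z, int act) {
  if (act == 0) return z;                         // none
  if (act == 1) { double s = 1.0 / (1.0 + std::exp(-z)); return z * s; }  // silu
  if (act == 2) return z > 0 ? z : 0.0;           // relu
  double s = 1.0 / (1.0 + std::exp(-z));          // sigmoid
  return s;
}

static inline double act_grad(double z, int act) {
  if (act == 0) return 1.0;
  if (act == 1) {
    double s = 1.0 / (1.0 + std::exp(-z));
    return s * (1.0 + z * (1.0 - s));
  }
  if (act == 2) return z > 0 ? 1.0 : 0.0;
  double s = 1.0 / (1.0 + std::exp(-z));
  return s * (1.0 - s);
}

// elementwise activation (act codes: 0 none, 1 silu, 2 relu, 3 sigmoid)
// [[Rcpp::export]]
NumericVector cpp_act_fw(NumericVector z, int act) {
  NumericVector y((R_xlen_t)z.size());
  y.attr("dim") = z.attr("dim");
  for (R_xlen_t i = 0; i < z.size(); ++i) y[i] = act_apply(z[i], act);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_act_bw(NumericVector gy, NumericVector z, int act) {
  NumericVector g((R_xlen_t)z.size());
  g.attr("dim") = z.attr("dim");
  for (R_xlen_t i = 0; i < z.size(); ++i) g[i] = gy[i] * act_grad(z[i], act);
  return g;
}

// fused affine-free batch norm + activation; returns post-activation y and
// the normalised pre-activation xhat (needed for backward)
// [[Rcpp::export]]
List cpp_bnact_fw(NumericVector x, NumericVector rmean, NumericVector rvar,
                  double eps, double momentum, bool train, int act) {
  IntegerVector xd = dims_of(x);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  R_xlen_t M = (R_xlen_t)N * H * W;
  NumericVector y((R_xlen_t)x.size()), xhat((R_xlen_t)x.size());
  y.attr("dim") = xd; xhat.attr("dim") = xd;
  NumericVector mu(C), invstd(C), nrm(C), nrv(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      double sum = 0.0, sum2 = 0.0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double* px = &x[IX(0, c, h, w, N, C, H)];
          for (int n = 0; n < N; ++n) { sum += px[n]; sum2 += px[n] * px[n]; }
        }
      double m = sum / M, var = sum2 / M - m * m;
      if (var < 0) var = 0;
      mu[c] = m;
      invstd[c] = 1.0 / std::sqrt(var + eps);
      nrm[c] = (1 - momentum) * rmean[c] + momentum * m;
      double ub = M > 1 ? var * M / (M - 1.0) : var;
      nrv[c] = (1 - momentum) * rvar[c] + momentum * ub;
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rmean[c];
      invstd[c] = 1.0 / std::sqrt(rvar[c] + eps);
      nrm[c] = rmean[c]; nrv[c] = rvar[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    double m = mu[c], is = invstd[c];
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        R_xlen_t base = IX(0, c, h, w, N, C, H);
        for (int n = 0; n < N; ++n) {
          double xh = (x[base + n] - m) * is;
          xhat[base + n] = xh;
          y[base + n] = act_apply(xh, act);
        }
      }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// [[Rcpp::export]]
NumericVector cpp_bnact_bw(NumericVector gy, NumericVector xhat,
                           NumericVector invstd, bool train, int act) {
  IntegerVector xd = dims_of(gy);
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  R_xlen_t M = (R_xlen_t)N * H * W;
  NumericVector gx((R_xlen_t)gy.size());
  gx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double is = invstd[c];
    if (train) {
      double sg = 0.0, sgx = 0.0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          R_xlen_t base = IX(0, c, h, w, N, C, H);
          for (int n = 0; n < N; ++n) {
            double gz = gy[base + n] * act_grad(xhat[base + n], act);
            gx[base + n] = gz;      // stash gz temporarily
            sg += gz; sgx += gz * xhat[base + n];
          }
        }
      double mg = sg / M, mgx = sgx / M;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          R_xlen_t base = IX(0, c, h, w, N, C, H);
          for (int n = 0; n < N; ++n)
            gx[base + n] = is * (gx[base + n] - mg -
                                 xhat[base + n] * mgx);
        }
    } else {
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          R_xlen_t base = IX(0, c, h, w, N, C, H);
          for (int n = 0; n < N; ++n)
            gx[base + n] = is * gy[base + n] *
              act_grad(xhat[base + n], act);
        }
    }
  }
  return gx;
}

// softmax over the tap axis (dim 2) of [N, K2, H, W]
// [[Rcpp::export]]
NumericVector cpp_softmax_taps(NumericVector a) {
  IntegerVector ad = dims_of(a);
  int N = ad[0], K2 = ad[1], H = ad[2], W = ad[3];
  NumericVector p((R_xlen_t)a.size());
  p.attr("dim") = ad;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int n = 0; n < N; ++n) {
        double m = R_NegInf;
        for (int t = 0; t < K2; ++t)
          m = std::max(m, (double)a[IX(n, t, h, w, N, K2, H)]);
        double s = 0.0;
        for (int t = 0; t < K2; ++t) {
          double e = std::exp(a[IX(n, t, h, w, N, K2, H)] - m);
          p[IX(n, t, h, w, N, K2, H)] = e;
          s += e;
        }
        for (int t = 0; t < K2; ++t)
          p[IX(n, t, h, w, N, K2, H)] /= s;
      }
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_softmax_taps_bw(NumericVector p, NumericVector gk) {
  IntegerVector ad = dims_of(p);
  int N = ad[0], K2 = ad[1], H = ad[2], W = ad[3];
  NumericVector g((R_xlen_t)p.size());
  g.attr("dim") = ad;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int n = 0; n < N; ++n) {
        double dot = 0.0;
        for (int t = 0; t < K2; ++t)
          dot += p[IX(n, t, h, w, N, K2, H)] * gk[IX(n, t, h, w, N, K2, H)];
        for (int t = 0; t < K2; ++t) {
          R_xlen_t i = IX(n, t, h, w, N, K2, H);
          g[i] = p[i] * (gk[i] - dot);
        }
      }
  return g;
}
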