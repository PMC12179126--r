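#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// All cubes are band-major R arrays with dim (D, H, W): the spectral axis is
// the fastest-varying index, so the inner loops over kernel depth touch
// contiguous memory.

static inline void get_dims3(const NumericVector &x, int &d, int &h, int &w) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("expected a 3-axis array");
  d = dm[0]; h = dm[1]; w = dm[2];
}

// Copy x into a zero-padded buffer of dims (D+2pd, H+2ph, W+2pw).
static std::vector<double> pad3(const double *x, int D, int H, int W,
                                int pd, int ph, int pw,
                                int &Dp, int &Hp, int &Wp) {
  Dp = D + 2 * pd; Hp = H + 2 * ph; Wp = W + 2 * pw;
  std::vector<double> p((size_t)Dp * Hp * Wp, 0.0);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      std::memcpy(&p[(size_t)pd + (size_t)Dp * ((h + ph) + (size_t)Hp * (w + pw))],
                  &x[(size_t)D * (h + (size_t)H * w)], sizeof(double) * D);
  return p;
}

// 3D cross-correlation (deep-learning convention, no kernel flip) of a
// single-channel cube with kernel k (dims kd,kh,kw), zero padding (pd,ph,pw),
// stride 1. Output dims: D+2pd-kd+1 etc.
// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector k, IntegerVector pad) {
  int D, H, W, kd, kh, kw;
  get_dims3(x, D, H, W); get_dims3(k, kd, kh, kw);
  int pd = pad[0], ph = pad[1], pw = pad[2];
  int Dp, Hp, Wp;
  std::vector<double> p = pad3(REAL(x), D, H, W, pd, ph, pw, Dp, Hp, Wp);
  int Do = Dp - kd + 1, Ho = Hp - kh + 1, Wo = Wp - kw + 1;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  NumericVector y((size_t)Do * Ho * Wo);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo);
  double *yp = REAL(y);
  const double *kp = REAL(k);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double *__restrict ycol = &yp[(size_t)Do * (ho + (size_t)Ho * wo)];
      for (int c = 0; c < kw; ++c) {
        for (int b = 0; b < kh; ++b) {
          const double *__restrict pcol = &p[(size_t)Dp * ((ho + b) + (size_t)Hp * (wo + c))];
          const double *__restrict krow = &kp[(size_t)kd * (b + (size_t)kh * c)];
          for (int a = 0; a < kd; ++a) {
            const double kv = krow[a];
            const double *__restrict src = pcol + a;
            for (int i = 0; i < Do; ++i) ycol[i] += kv * src[i];
          }
        }
      }
    }
  }
  return y;
}

// Gradient of conv3d_fwd w.r.t. the kernel: dK(a,b,c) = sum_ijk dY(i,j,k) *
// Xpad(i+a, j+b, k+c).
// [[Rcpp::export(name = ".conv3d_bwd_kernel")]]
NumericVector conv3d_bwd_kernel_cpp(NumericVector x, NumericVector dy,
                                    IntegerVector kdim, IntegerVector pad) {
  int D, H, W, Do, Ho, Wo;
  get_dims3(x, D, H, W); get_dims3(dy, Do, Ho, Wo);
  int kd = kdim[0], kh = kdim[1], kw = kdim[2];
  int pd = pad[0], ph = pad[1], pw = pad[2];
  int Dp, Hp, Wp;
  std::vector<double> p = pad3(REAL(x), D, H, W, pd, ph, pw, Dp, Hp, Wp);
  NumericVector dk((size_t)kd * kh * kw);
  dk.attr("dim") = IntegerVector::create(kd, kh, kw);
  double *dkp = REAL(dk);
  const double *dyp = REAL(dy);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double *__restrict dycol = &dyp[(size_t)Do * (ho + (size_t)Ho * wo)];
      for (int c = 0; c < kw; ++c) {
        for (int b = 0; b < kh; ++b) {
          const double *__restrict pcol = &p[(size_t)Dp * ((ho + b) + (size_t)Hp * (wo + c))];
          double *__restrict dkrow = &dkp[(size_t)kd * (b + (size_t)kh * c)];
          for (int a = 0; a < kd; ++a) {
            const double *__restrict src = pcol + a;
            double acc = 0.0;
            for (int i = 0; i < Do; ++i) acc += dycol[i] * src[i];
            dkrow[a] += acc;
          }
        }
      }
    }
  }
  return dk;
}

// Gradient w.r.t. the input: scatter dY through the kernel into the padded
// frame, then crop the padding.
// [[Rcpp::export(name = ".conv3d_bwd_input")]]
NumericVector conv3d_bwd_input_cpp(NumericVector dy, NumericVector k,
                                   IntegerVector xdim, IntegerVector pad) {
  int Do, Ho, Wo, kd, kh, kw;
  get_dims3(dy, Do, Ho, Wo); get_dims3(k, kd, kh, kw);
  int D = xdim[0], H = xdim[1], W = xdim[2];
  int pd = pad[0], ph = pad[1], pw = pad[2];
  int Dp = D + 2 * pd, Hp = H + 2 * ph, Wp = W + 2 * pw;
  std::vector<double> dp((size_t)Dp * Hp * Wp, 0.0);
  const double *dyp = REAL(dy);
  const double *kp = REAL(k);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double *__restrict dycol = &dyp[(size_t)Do * (ho + (size_t)Ho * wo)];
      for (int c = 0; c < kw; ++c) {
        for (int b = 0; b < kh; ++b) {
          double *__restrict pcol = &dp[(size_t)Dp * ((ho + b) + (size_t)Hp * (wo + c))];
          const double *__restrict krow = &kp[(size_t)kd * (b + (size_t)kh * c)];
          for (int a = 0; a < kd; ++a) {
            const double kv = krow[a];
            double *__restrict dst = pcol + a;
            for (int i = 0; i < Do; ++i) dst[i] += kv * dycol[i];
          }
        }
      }
    }
  }
  NumericVector dx((size_t)D * H * W);
  dx.attr("dim") = IntegerVector::create(D, H, W);
  double *dxp = REAL(dx);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      std::memcpy(&dxp[(size_t)D * (h + (size_t)H * w)],
                  &dp[(size_t)pd + (size_t)Dp * ((h + ph) + (size_t)Hp * (w + pw))],
                  sizeof(double) * D);
  return dx;
}

// 2x2x2 max pooling with stride 2 and floor-mode output dims. Returns the
// pooled cube plus 1-based linear argmax indices into the input for backprop.
// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd_cpp(NumericVector x) {
  int D, H, W;
  get_dims3(x, D, H, W);
  int Do = D / 2, Ho = H / 2, Wo = W / 2;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("axis too small to pool");
  NumericVector y((size_t)Do * Ho * Wo);
  IntegerVector idx((size_t)Do * Ho * Wo);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  int *ip = INTEGER(idx);
  size_t o = 0;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int dz = 0; dz < Do; ++dz, ++o) {
        double best = -1e308; size_t besti = 0;
        for (int c = 0; c < 2; ++c)
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              size_t i = (size_t)(2 * dz + a) +
                         (size_t)D * ((2 * ho + b) + (size_t)H * (2 * wo + c));
              if (xp[i] > best) { best = xp[i]; besti = i; }
            }
        yp[o] = best;
        ip[o] = (int)(besti + 1);
      }
    }
  }
  return List::create(_["values"] = y, _["argmax"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd_cpp(NumericVector dy, IntegerVector argmax,
                                IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2]);
  dx.attr("dim") = xdim;
  double *dxp = REAL(dx);
  const double *dyp = REAL(dy);
  const int *ip = INTEGER(argmax);
  R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dxp[ip[i] - 1] += dyp[i];
  return dx;
}

// Connected-component labeling of a binary matrix, 4- or 8-connectivity,
// iterative flood fill. Returns an integer label matrix (0 = background),
// labels assigned in column-major scan order.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        ++next;
        stack.clear();
        stack.push_back(std::make_pair(r, c));
        lab(r, c) = next;
        while (!stack.empty()) {
          std::pair<int,int> p = stack.back();
          stack.pop_back();
          for (int k = 0; k < nn; ++k) {
            int rr = p.first + dr8[k], cc = p.second + dc8[k];
            if (rr >= 0 && rr < H && cc >= 0 && cc < W &&
                mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Single-pass mean/variance over a batch (list of equally sized arrays).
// [[Rcpp::export(name = ".bn_stats")]]
NumericVector bn_stats_cpp(List zs) {
  double sum = 0.0, sumsq = 0.0;
  size_t n = 0;
  for (int s = 0; s < zs.size(); ++s) {
    NumericVector z = zs[s];
    const double *__restrict zp = REAL(z);
    R_xlen_t m = z.size();
    double a = 0.0, b = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) { a += zp[i]; b += zp[i] * zp[i]; }
    sum += a; sumsq += b; n += m;
  }
  double mu = sum / n;
  return NumericVector::create(mu, sumsq / n - mu * mu);
}

// Fused batch norm (given mu/std) + affine + ReLU + 2x2x2 max pool over a
// batch. keep_cache stores the normalized activations and pool argmax for
// the backward pass.
// [[Rcpp::export(name = ".bn_relu_pool_fwd")]]
List bn_relu_pool_fwd_cpp(List zs, double mu, double stdv, double gamma,
                          double beta, bool keep_cache) {
  int n = zs.size();
  List pooled(n), argmax(n), xhat(n);
  std::vector<double> act;
  for (int s = 0; s < n; ++s) {
    NumericVector z = zs[s];
    int D, H, W;
    get_dims3(z, D, H, W);
    const double *__restrict zp = REAL(z);
    R_xlen_t m = z.size();
    act.resize(m);
    double *__restrict ap = &act[0];
    double *xp = NULL;
    if (keep_cache) {
      NumericVector xh(m);
      xh.attr("dim") = z.attr("dim");
      xhat[s] = xh;
      xp = REAL(xh);
    }
    const double inv = 1.0 / stdv;
    for (R_xlen_t i = 0; i < m; ++i) {
      double v = (zp[i] - mu) * inv;
      if (keep_cache) xp[i] = v;
      double a = gamma * v + beta;
      ap[i] = a > 0 ? a : 0;
    }
    int Do = D / 2, Ho = H / 2, Wo = W / 2;
    if (Do < 1 || Ho < 1 || Wo < 1) stop("axis too small to pool");
    NumericVector y((size_t)Do * Ho * Wo);
    y.attr("dim") = IntegerVector::create(Do, Ho, Wo);
    IntegerVector idx((size_t)Do * Ho * Wo);
    double *__restrict yp = REAL(y);
    int *__restrict ip = INTEGER(idx);
    size_t o = 0;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int dz = 0; dz < Do; ++dz, ++o) {
          double best = -1e308; size_t besti = 0;
          for (int c = 0; c < 2; ++c)
            for (int b2 = 0; b2 < 2; ++b2)
              for (int a2 = 0; a2 < 2; ++a2) {
                size_t i = (size_t)(2 * dz + a2) +
                           (size_t)D * ((2 * ho + b2) + (size_t)H * (2 * wo + c));
                if (ap[i] > best) { best = ap[i]; besti = i; }
              }
          yp[o] = best;
          ip[o] = (int)(besti + 1);
        }
    pooled[s] = y;
    if (keep_cache) argmax[s] = idx;
  }
  return List::create(_["pooled"] = pooled, _["argmax"] = argmax,
                      _["xhat"] = xhat);
}

// Fused backward of pool + ReLU + batch norm. Returns per-sample gradients
// w.r.t. the pre-norm convolution outputs plus dgamma/dbeta.
// [[Rcpp::export(name = ".bn_relu_pool_bwd")]]
List bn_relu_pool_bwd_cpp(List dpooled, List argmax, List xhat, double gamma,
                          double beta, double stdv) {
  int n = dpooled.size();
  List dz(n);
  double dgamma = 0.0, dbeta = 0.0, s1 = 0.0, s2 = 0.0;
  double N = 0.0;
  // pass 1: scatter pool grads, ReLU mask, dxhat (stored in dz buffers)
  for (int s = 0; s < n; ++s) {
    NumericVector xh = xhat[s];
    NumericVector dy = dpooled[s];
    IntegerVector idx = argmax[s];
    R_xlen_t m = xh.size();
    N += m;
    NumericVector g(m);
    g.attr("dim") = xh.attr("dim");
    double *__restrict gp = REAL(g);
    const double *__restrict dyp = REAL(dy);
    const int *__restrict ip = INTEGER(idx);
    R_xlen_t np = dy.size();
    for (R_xlen_t i = 0; i < np; ++i) gp[ip[i] - 1] += dyp[i];
    const double *__restrict xp = REAL(xh);
    for (R_xlen_t i = 0; i < m; ++i) {
      double active = (gamma * xp[i] + beta) > 0 ? 1.0 : 0.0;
      double dbn = gp[i] * active;
      dgamma += dbn * xp[i];
      dbeta += dbn;
      double dxh = dbn * gamma;
      gp[i] = dxh;
      s1 += dxh;
      s2 += dxh * xp[i];
    }
    dz[s] = g;
  }
  // pass 2: complete the batch-norm input gradient
  const double inv = 1.0 / stdv;
  for (int s = 0; s < n; ++s) {
    NumericVector g = dz[s];
    NumericVector xh = xhat[s];
    double *__restrict gp = REAL(g);
    const double *__restrict xp = REAL(xh);
    R_xlen_t m = g.size();
    for (R_xlen_t i = 0; i < m; ++i)
      gp[i] = (gp[i] - s1 / N - xp[i] * (s2 / N)) * inv;
  }
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
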