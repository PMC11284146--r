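// Numerical kernels for the tensor engine.
//
// Tensor memory layout: numeric arrays with dim = c(H, W, C, N), i.e. the
// element (h, w, c, n) lives at h + H*(w + W*(c + C*n)) (R column-major).
// Convolution weights: dim = c(k, k, Cin/groups, Cout).
// Transposed-convolution weights: dim = c(k, k, Cout/groups, Cin).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector make4(int a, int b, int c, int d) {
  NumericVector y((R_xlen_t)a * b * c * d);
  y.attr("dim") = IntegerVector::create(a, b, c, d);
  return y;
}

static inline int outsize(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// ---------------------------------------------------------------- im2col ----
// col is (S_out x K), K = k*k*cin_pg, column index idx = i + k*(j + k*ci)
static void im2col(const double* x, int H, int W, int cin_pg,
                   int k, int stride, int pad, int Hout, int Wout,
                   arma::mat& col) {
  const int S = H * W;
  if (stride == 1) {
    for (int ci = 0; ci < cin_pg; ++ci) {
      const double* xp = x + (size_t)S * ci;
      for (int j = 0; j < k; ++j) {
        for (int i = 0; i < k; ++i) {
          const int idx = i + k * (j + k * ci);
          double* cp = col.colptr(idx);
          const int h0 = std::max(0, pad - i);
          const int h1 = std::min(Hout, H + pad - i);
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo + j - pad;
            double* cq = cp + (size_t)Hout * wo;
            if (wi < 0 || wi >= W) {
              std::fill(cq, cq + Hout, 0.0);
              continue;
            }
            if (h0 > 0) std::fill(cq, cq + h0, 0.0);
            if (h1 < Hout) std::fill(cq + h1, cq + Hout, 0.0);
            if (h1 > h0)
              std::memcpy(cq + h0, xp + (h0 + i - pad) + (size_t)H * wi,
                          sizeof(double) * (h1 - h0));
          }
        }
      }
    }
    return;
  }
  for (int ci = 0; ci < cin_pg; ++ci) {
    const double* xp = x + (size_t)S * ci;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int idx = i + k * (j + k * ci);
        double* cp = col.colptr(idx);
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride + j - pad;
          const bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride + i - pad;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xp[hi + H * wi];
            cp[ho + Hout * wo] = v;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int cin_pg,
                       int k, int stride, int pad, int Hout, int Wout,
                       double* gx) {
  const int S = H * W;
  if (stride == 1) {
    for (int ci = 0; ci < cin_pg; ++ci) {
      double* gp = gx + (size_t)S * ci;
      for (int j = 0; j < k; ++j) {
        for (int i = 0; i < k; ++i) {
          const int idx = i + k * (j + k * ci);
          const double* cp = col.colptr(idx);
          const int h0 = std::max(0, pad - i);
          const int h1 = std::min(Hout, H + pad - i);
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo + j - pad;
            if (wi < 0 || wi >= W) continue;
            const double* cq = cp + h0 + (size_t)Hout * wo;
            double* gq = gp + (h0 + i - pad) + (size_t)H * wi;
            for (int ho = h0; ho < h1; ++ho) *gq++ += *cq++;
          }
        }
      }
    }
    return;
  }
  for (int ci = 0; ci < cin_pg; ++ci) {
    double* gp = gx + (size_t)S * ci;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int idx = i + k * (j + k * ci);
        const double* cp = col.colptr(idx);
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride + j - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride + i - pad;
            if (hi < 0 || hi >= H) continue;
            gp[hi + H * wi] += cp[ho + Hout * wo];
          }
        }
      }
    }
  }
}


// reusable scratch buffers for im2col matrices (single-threaded R)
static arma::mat& scratch_mat(int which, size_t rows, size_t cols) {
  static arma::mat bufs[4];
  arma::mat& m = bufs[which];
  if (m.n_rows != rows || m.n_cols != cols) m.set_size(rows, cols);
  return m;
}

// im2col writing into rows [row0, row0+S_out) of a tall (S_out*N x K) matrix
static void im2col_block(const double* x, int H, int W, int cin_pg,
                         int k, int stride, int pad, int Hout, int Wout,
                         arma::mat& col, size_t row0) {
  const int S = H * W;
  if (stride == 1) {
    for (int ci = 0; ci < cin_pg; ++ci) {
      const double* xp = x + (size_t)S * ci;
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < k; ++i) {
          const int idx = i + k * (j + k * ci);
          double* cp = col.colptr(idx) + row0;
          const int h0 = std::max(0, pad - i);
          const int h1 = std::min(Hout, H + pad - i);
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo + j - pad;
            double* cq = cp + (size_t)Hout * wo;
            if (wi < 0 || wi >= W) { std::fill(cq, cq + Hout, 0.0); continue; }
            if (h0 > 0) std::fill(cq, cq + h0, 0.0);
            if (h1 < Hout) std::fill(cq + h1, cq + Hout, 0.0);
            if (h1 > h0)
              std::memcpy(cq + h0, xp + (h0 + i - pad) + (size_t)H * wi,
                          sizeof(double) * (h1 - h0));
          }
        }
    }
    return;
  }
  for (int ci = 0; ci < cin_pg; ++ci) {
    const double* xp = x + (size_t)S * ci;
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i) {
        const int idx = i + k * (j + k * ci);
        double* cp = col.colptr(idx) + row0;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride + j - pad;
          const bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride + i - pad;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xp[hi + H * wi];
            cp[ho + Hout * wo] = v;
          }
        }
      }
  }
}

static void col2im_add_block(const arma::mat& col, int H, int W, int cin_pg,
                             int k, int stride, int pad, int Hout, int Wout,
                             double* gx, size_t row0) {
  const int S = H * W;
  for (int ci = 0; ci < cin_pg; ++ci) {
    double* gp = gx + (size_t)S * ci;
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i) {
        const int idx = i + k * (j + k * ci);
        const double* cp = col.colptr(idx) + row0;
        if (stride == 1) {
          const int h0 = std::max(0, pad - i);
          const int h1 = std::min(Hout, H + pad - i);
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo + j - pad;
            if (wi < 0 || wi >= W) continue;
            const double* cq = cp + h0 + (size_t)Hout * wo;
            double* gq = gp + (h0 + i - pad) + (size_t)H * wi;
            for (int ho = h0; ho < h1; ++ho) *gq++ += *cq++;
          }
        } else {
          for (int wo = 0; wo < Wout; ++wo) {
            const int wi = wo * stride + j - pad;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Hout; ++ho) {
              const int hi = ho * stride + i - pad;
              if (hi < 0 || hi >= H) continue;
              gp[hi + H * wi] += cp[ho + Hout * wo];
            }
          }
        }
      }
  }
}

// ------------------------------------------------------------ convolution ---
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xd,
                           NumericVector w, Nullable<NumericVector> bias,
                           int k, int stride, int pad, int groups, int cout) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int cin_pg = C / groups, cout_pg = cout / groups;
  const int Hout = outsize(H, k, stride, pad), Wout = outsize(W, k, stride, pad);
  const int S = H * W, So = Hout * Wout;
  NumericVector y = make4(Hout, Wout, cout, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  const double* wp = w.begin();

  if (cin_pg == 1 && cout_pg == 1 && stride == 1) {   // depthwise, offset order
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double* xq = xp + (size_t)S * (c + (size_t)C * n);
        double* yq = yp + (size_t)So * (c + (size_t)C * n);
        const double* wq = wp + (size_t)k * k * c;
        for (int j = 0; j < k; ++j)
          for (int i = 0; i < k; ++i) {
            const double wv = wq[i + k * j];
            if (wv == 0.0) continue;
            for (int wo = 0; wo < Wout; ++wo) {
              const int wi = wo + j - pad;
              if (wi < 0 || wi >= W) continue;
              const int h0 = std::max(0, pad - i);
              const int h1 = std::min(Hout, H + pad - i);
              const double* xc = xq + (h0 + i - pad) + H * wi;
              double* yc = yq + h0 + Hout * wo;
              for (int ho = h0; ho < h1; ++ho) *yc++ += wv * *xc++;
            }
          }
      }
  } else if (cin_pg == 1 && cout_pg == 1) {           // depthwise strided
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double* xq = xp + (size_t)S * (c + (size_t)C * n);
        double* yq = yp + (size_t)So * (c + (size_t)C * n);
        const double* wq = wp + (size_t)k * k * c;
        for (int wo = 0; wo < Wout; ++wo)
          for (int ho = 0; ho < Hout; ++ho) {
            double acc = 0.0;
            for (int j = 0; j < k; ++j) {
              const int wi = wo * stride + j - pad;
              if (wi < 0 || wi >= W) continue;
              for (int i = 0; i < k; ++i) {
                const int hi = ho * stride + i - pad;
                if (hi < 0 || hi >= H) continue;
                acc += xq[hi + H * wi] * wq[i + k * j];
              }
            }
            yq[ho + Hout * wo] = acc;
          }
      }
  } else if (k == 1 && stride == 1 && pad == 0 && groups == 1 && S > 4096) {
    arma::mat Wm(const_cast<double*>(wp), C, cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(xp) + (size_t)S * C * n, S, C, false, true);
      arma::mat Y(yp + (size_t)S * cout * n, S, cout, false, true);
      Y = X * Wm;
    }
  } else if (k == 1 && stride == 1 && pad == 0 && groups == 1) {
    // gather all samples into one (S*N x C) matrix for a single GEMM
    arma::mat Wm(const_cast<double*>(wp), C, cout, false, true);
    arma::mat X2((size_t)S * N, C);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c)
        std::memcpy(X2.colptr(c) + (size_t)S * n,
                    xp + (size_t)S * (c + (size_t)C * n), sizeof(double) * S);
    arma::mat Y2 = X2 * Wm;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c)
        std::memcpy(yp + (size_t)So * (c + (size_t)cout * n),
                    Y2.colptr(c) + (size_t)So * n, sizeof(double) * So);
  } else if (So <= 256) {
    // small outputs: batch all samples into one GEMM per group
    const int K = k * k * cin_pg;
    arma::mat& col = scratch_mat(0, (size_t)So * N, K);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n) {
        const double* xg = xp + (size_t)S * ((size_t)g * cin_pg + (size_t)C * n);
        im2col_block(xg, H, W, cin_pg, k, stride, pad, Hout, Wout, col,
                     (size_t)So * n);
      }
      arma::mat Wg(const_cast<double*>(wp) + (size_t)K * g * cout_pg, K, cout_pg,
                   false, true);
      arma::mat Y2 = col * Wg;
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < cout_pg; ++c)
          std::memcpy(yp + (size_t)So * ((size_t)(g * cout_pg + c) +
                                         (size_t)cout * n),
                      Y2.colptr(c) + (size_t)So * n, sizeof(double) * So);
    }
  } else {
    const int K = k * k * cin_pg;
    arma::mat& col = scratch_mat(0, So, K);
    for (int n = 0; n < N; ++n)
      for (int g = 0; g < groups; ++g) {
        const double* xg = xp + (size_t)S * ((size_t)g * cin_pg + (size_t)C * n);
        im2col(xg, H, W, cin_pg, k, stride, pad, Hout, Wout, col);
        arma::mat Wg(const_cast<double*>(wp) + (size_t)K * g * cout_pg, K, cout_pg,
                     false, true);
        arma::mat Y(yp + (size_t)So * ((size_t)g * cout_pg + (size_t)cout * n),
                    So, cout_pg, false, true);
        Y = col * Wg;
      }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        double* yq = yp + (size_t)So * (c + (size_t)cout * n);
        const double bv = b[c];
        for (int s = 0; s < So; ++s) yq[s] += bv;
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, IntegerVector xd,
                  NumericVector w, NumericVector gy,
                  int k, int stride, int pad, int groups, int cout,
                  bool has_bias) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int cin_pg = C / groups, cout_pg = cout / groups;
  const int Hout = outsize(H, k, stride, pad), Wout = outsize(W, k, stride, pad);
  const int S = H * W, So = Hout * Wout;
  NumericVector gx = make4(H, W, C, N);
  NumericVector gw(w.size());
  NumericVector gb(has_bias ? cout : 1);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  const double* wp = w.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();

  if (cin_pg == 1 && cout_pg == 1 && stride == 1) {   // depthwise, offset order
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double* xq = xp + (size_t)S * (c + (size_t)C * n);
        const double* gq = gyp + (size_t)So * (c + (size_t)C * n);
        double* gxq = gxp + (size_t)S * (c + (size_t)C * n);
        const double* wq = wp + (size_t)k * k * c;
        double* gwq = gwp + (size_t)k * k * c;
        for (int j = 0; j < k; ++j)
          for (int i = 0; i < k; ++i) {
            const double wv = wq[i + k * j];
            double gw = 0.0;
            for (int wo = 0; wo < Wout; ++wo) {
              const int wi = wo + j - pad;
              if (wi < 0 || wi >= W) continue;
              const int h0 = std::max(0, pad - i);
              const int h1 = std::min(Hout, H + pad - i);
              const double* gc = gq + h0 + Hout * wo;
              const double* xc = xq + (h0 + i - pad) + H * wi;
              double* gxc = gxq + (h0 + i - pad) + H * wi;
              for (int ho = h0; ho < h1; ++ho) {
                const double g = *gc++;
                gw += g * *xc++;
                *gxc++ += g * wv;
              }
            }
            gwq[i + k * j] += gw;
          }
      }
  } else if (cin_pg == 1 && cout_pg == 1) {           // depthwise strided
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double* xq = xp + (size_t)S * (c + (size_t)C * n);
        const double* gq = gyp + (size_t)So * (c + (size_t)C * n);
        double* gxq = gxp + (size_t)S * (c + (size_t)C * n);
        const double* wq = wp + (size_t)k * k * c;
        double* gwq = gwp + (size_t)k * k * c;
        for (int wo = 0; wo < Wout; ++wo)
          for (int ho = 0; ho < Hout; ++ho) {
            const double g = gq[ho + Hout * wo];
            if (g == 0.0) continue;
            for (int j = 0; j < k; ++j) {
              const int wi = wo * stride + j - pad;
              if (wi < 0 || wi >= W) continue;
              for (int i = 0; i < k; ++i) {
                const int hi = ho * stride + i - pad;
                if (hi < 0 || hi >= H) continue;
                gxq[hi + H * wi] += g * wq[i + k * j];
                gwq[i + k * j] += g * xq[hi + H * wi];
              }
            }
          }
      }
  } else if (k == 1 && stride == 1 && pad == 0 && groups == 1 && S > 4096) {
    arma::mat Wm(const_cast<double*>(wp), C, cout, false, true);
    arma::mat GW(gwp, C, cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(xp) + (size_t)S * C * n, S, C, false, true);
      arma::mat GY(const_cast<double*>(gyp) + (size_t)S * cout * n, S, cout,
                   false, true);
      arma::mat GX(gxp + (size_t)S * C * n, S, C, false, true);
      GW += X.t() * GY;
      GX = GY * Wm.t();
    }
  } else if (k == 1 && stride == 1 && pad == 0 && groups == 1) {
    arma::mat Wm(const_cast<double*>(wp), C, cout, false, true);
    arma::mat GW(gwp, C, cout, false, true);
    arma::mat X2((size_t)S * N, C), GY2((size_t)S * N, cout);
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c)
        std::memcpy(X2.colptr(c) + (size_t)S * n,
                    xp + (size_t)S * (c + (size_t)C * n), sizeof(double) * S);
      for (int c = 0; c < cout; ++c)
        std::memcpy(GY2.colptr(c) + (size_t)S * n,
                    gyp + (size_t)S * (c + (size_t)cout * n), sizeof(double) * S);
    }
    GW += X2.t() * GY2;
    arma::mat GX2 = GY2 * Wm.t();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c)
        std::memcpy(gxp + (size_t)S * (c + (size_t)C * n),
                    GX2.colptr(c) + (size_t)S * n, sizeof(double) * S);
  } else if (So <= 256) {
    const int K = k * k * cin_pg;
    arma::mat& col = scratch_mat(0, (size_t)So * N, K);
    arma::mat& GY2 = scratch_mat(1, (size_t)So * N, cout_pg);
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < N; ++n) {
        const double* xg = xp + (size_t)S * ((size_t)g * cin_pg + (size_t)C * n);
        im2col_block(xg, H, W, cin_pg, k, stride, pad, Hout, Wout, col,
                     (size_t)So * n);
        for (int c = 0; c < cout_pg; ++c)
          std::memcpy(GY2.colptr(c) + (size_t)So * n,
                      gyp + (size_t)So * ((size_t)(g * cout_pg + c) +
                                          (size_t)cout * n),
                      sizeof(double) * So);
      }
      arma::mat Wg(const_cast<double*>(wp) + (size_t)K * g * cout_pg, K, cout_pg,
                   false, true);
      arma::mat GWg(gwp + (size_t)K * g * cout_pg, K, cout_pg, false, true);
      GWg += col.t() * GY2;
      arma::mat gcol = GY2 * Wg.t();
      for (int n = 0; n < N; ++n) {
        double* gxg = gxp + (size_t)S * ((size_t)g * cin_pg + (size_t)C * n);
        col2im_add_block(gcol, H, W, cin_pg, k, stride, pad, Hout, Wout, gxg,
                         (size_t)So * n);
      }
    }
  } else {
    const int K = k * k * cin_pg;
    arma::mat& col = scratch_mat(0, So, K);
    arma::mat& gcol = scratch_mat(1, So, K);
    for (int n = 0; n < N; ++n)
      for (int g = 0; g < groups; ++g) {
        const double* xg = xp + (size_t)S * ((size_t)g * cin_pg + (size_t)C * n);
        im2col(xg, H, W, cin_pg, k, stride, pad, Hout, Wout, col);
        arma::mat Wg(const_cast<double*>(wp) + (size_t)K * g * cout_pg, K, cout_pg,
                     false, true);
        arma::mat GWg(gwp + (size_t)K * g * cout_pg, K, cout_pg, false, true);
        arma::mat GY(const_cast<double*>(gyp) +
                         (size_t)So * ((size_t)g * cout_pg + (size_t)cout * n),
                     So, cout_pg, false, true);
        GWg += col.t() * GY;
        gcol = GY * Wg.t();
        double* gxg = gxp + (size_t)S * ((size_t)g * cin_pg + (size_t)C * n);
        col2im_add(gcol, H, W, cin_pg, k, stride, pad, Hout, Wout, gxg);
      }
  }
  if (has_bias) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        const double* gq = gyp + (size_t)So * (c + (size_t)cout * n);
        double acc = 0.0;
        for (int s = 0; s < So; ++s) acc += gq[s];
        gb[c] += acc;
      }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// -------------------------------------------------- transposed convolution --
// Hout = (H - 1) * stride + k (no padding, no output padding)
// [[Rcpp::export]]
NumericVector cpp_convtr_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, Nullable<NumericVector> bias,
                             int k, int stride, int groups, int cout) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int cin_pg = C / groups, cout_pg = cout / groups;
  const int Hout = (H - 1) * stride + k, Wout = (W - 1) * stride + k;
  const int S = H * W, So = Hout * Wout;
  const int K = k * k * cout_pg;
  NumericVector y = make4(Hout, Wout, cout, N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  arma::mat& col = scratch_mat(2, S, K);
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      arma::mat X(const_cast<double*>(xp) +
                      (size_t)S * ((size_t)g * cin_pg + (size_t)C * n),
                  S, cin_pg, false, true);
      arma::mat Wg(const_cast<double*>(wp) + (size_t)K * g * cin_pg, K, cin_pg,
                   false, true);
      col = X * Wg.t();
      double* yg = yp + (size_t)So * ((size_t)g * cout_pg + (size_t)cout * n);
      for (int co = 0; co < cout_pg; ++co)
        for (int j = 0; j < k; ++j)
          for (int i = 0; i < k; ++i) {
            const int idx = i + k * (j + k * co);
            const double* cp = col.colptr(idx);
            double* yq = yg + (size_t)So * co;
            for (int wi = 0; wi < W; ++wi) {
              const int wo = wi * stride + j;
              for (int hi = 0; hi < H; ++hi)
                yq[(hi * stride + i) + Hout * wo] += cp[hi + H * wi];
            }
          }
    }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        double* yq = yp + (size_t)So * (c + (size_t)cout * n);
        const double bv = b[c];
        for (int s = 0; s < So; ++s) yq[s] += bv;
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convtr_bwd(NumericVector x, IntegerVector xd,
                    NumericVector w, NumericVector gy,
                    int k, int stride, int groups, int cout, bool has_bias) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int cin_pg = C / groups, cout_pg = cout / groups;
  const int Hout = (H - 1) * stride + k, Wout = (W - 1) * stride + k;
  const int S = H * W, So = Hout * Wout;
  const int K = k * k * cout_pg;
  NumericVector gx = make4(H, W, C, N);
  NumericVector gw(w.size());
  NumericVector gb(has_bias ? cout : 1);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gyp = gy.begin();
  arma::mat& gcol = scratch_mat(2, S, K);
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      const double* gyg = gyp + (size_t)So * ((size_t)g * cout_pg + (size_t)cout * n);
      for (int co = 0; co < cout_pg; ++co)
        for (int j = 0; j < k; ++j)
          for (int i = 0; i < k; ++i) {
            const int idx = i + k * (j + k * co);
            double* cp = gcol.colptr(idx);
            const double* gq = gyg + (size_t)So * co;
            for (int wi = 0; wi < W; ++wi) {
              const int wo = wi * stride + j;
              for (int hi = 0; hi < H; ++hi)
                cp[hi + H * wi] = gq[(hi * stride + i) + Hout * wo];
            }
          }
      arma::mat X(const_cast<double*>(xp) +
                      (size_t)S * ((size_t)g * cin_pg + (size_t)C * n),
                  S, cin_pg, false, true);
      arma::mat Wg(const_cast<double*>(wp) + (size_t)K * g * cin_pg, K, cin_pg,
                   false, true);
      arma::mat GX(gx.begin() + (size_t)S * ((size_t)g * cin_pg + (size_t)C * n),
                   S, cin_pg, false, true);
      arma::mat GW(gw.begin() + (size_t)K * g * cin_pg, K, cin_pg, false, true);
      GX = gcol * Wg;
      GW += gcol.t() * X;
    }
  if (has_bias) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < cout; ++c) {
        const double* gq = gyp + (size_t)So * (c + (size_t)cout * n);
        double acc = 0.0;
        for (int s = 0; s < So; ++s) acc += gq[s];
        gb[c] += acc;
      }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// --------------------------------------------------------------- bilinear ---
// half-pixel sampling (align_corners = FALSE)
static inline void bilin_coef(int o, int in, int out, int& i0, int& i1, double& d) {
  double s = (o + 0.5) * (double)in / (double)out - 0.5;
  if (s < 0) s = 0;
  if (s > in - 1) s = in - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < in ? i0 + 1 : in - 1;
  d = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, IntegerVector xd,
                               int Hout, int Wout) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int S = H * W, So = Hout * Wout;
  NumericVector y = make4(Hout, Wout, C, N);
  std::vector<int> h0(Hout), h1(Hout), w0(Wout), w1(Wout);
  std::vector<double> dh(Hout), dw(Wout);
  for (int ho = 0; ho < Hout; ++ho) bilin_coef(ho, H, Hout, h0[ho], h1[ho], dh[ho]);
  for (int wo = 0; wo < Wout; ++wo) bilin_coef(wo, W, Wout, w0[wo], w1[wo], dw[wo]);
  const double* xp = x.begin();
  double* yp = y.begin();
  const int P = C * N;
  for (int p = 0; p < P; ++p) {
    const double* xq = xp + (size_t)S * p;
    double* yq = yp + (size_t)So * p;
    for (int wo = 0; wo < Wout; ++wo) {
      const int a = w0[wo] * H, b = w1[wo] * H;
      const double dx = dw[wo];
      for (int ho = 0; ho < Hout; ++ho) {
        const double dy = dh[ho];
        const double v00 = xq[h0[ho] + a], v10 = xq[h1[ho] + a];
        const double v01 = xq[h0[ho] + b], v11 = xq[h1[ho] + b];
        yq[ho + Hout * wo] = (1 - dy) * (1 - dx) * v00 + dy * (1 - dx) * v10 +
                             (1 - dy) * dx * v01 + dy * dx * v11;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gy, IntegerVector yd,
                               int Hin, int Win) {
  const int Hout = yd[0], Wout = yd[1], C = yd[2], N = yd[3];
  const int S = Hin * Win, So = Hout * Wout;
  NumericVector gx = make4(Hin, Win, C, N);
  std::vector<int> h0(Hout), h1(Hout), w0(Wout), w1(Wout);
  std::vector<double> dh(Hout), dw(Wout);
  for (int ho = 0; ho < Hout; ++ho) bilin_coef(ho, Hin, Hout, h0[ho], h1[ho], dh[ho]);
  for (int wo = 0; wo < Wout; ++wo) bilin_coef(wo, Win, Wout, w0[wo], w1[wo], dw[wo]);
  const double* gp = gy.begin();
  double* gq = gx.begin();
  const int P = C * N;
  for (int p = 0; p < P; ++p) {
    const double* g = gp + (size_t)So * p;
    double* o = gq + (size_t)S * p;
    for (int wo = 0; wo < Wout; ++wo) {
      const int a = w0[wo] * Hin, b = w1[wo] * Hin;
      const double dx = dw[wo];
      for (int ho = 0; ho < Hout; ++ho) {
        const double dy = dh[ho];
        const double v = g[ho + Hout * wo];
        o[h0[ho] + a] += (1 - dy) * (1 - dx) * v;
        o[h1[ho] + a] += dy * (1 - dx) * v;
        o[h0[ho] + b] += (1 - dy) * dx * v;
        o[h1[ho] + b] += dy * dx * v;
      }
    }
  }
  return gx;
}

// ---------------------------------------------------------------- maxpool ---
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even");
  const int Hout = H / 2, Wout = W / 2;
  const int S = H * W, So = Hout * Wout;
  NumericVector y = make4(Hout, Wout, C, N);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const int P = C * N;
  for (int p = 0; p < P; ++p) {
    const double* xq = xp + (size_t)S * p;
    double* yq = yp + (size_t)So * p;
    int* iq = ip + (size_t)So * p;
    for (int wo = 0; wo < Wout; ++wo)
      for (int ho = 0; ho < Hout; ++ho) {
        int best = (2 * ho) + H * (2 * wo);
        double bv = xq[best];
        const int cand[3] = {2 * ho + 1 + H * (2 * wo), 2 * ho + H * (2 * wo + 1),
                             2 * ho + 1 + H * (2 * wo + 1)};
        for (int t = 0; t < 3; ++t)
          if (xq[cand[t]] > bv) { bv = xq[cand[t]]; best = cand[t]; }
        yq[ho + Hout * wo] = bv;
        iq[ho + Hout * wo] = best;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector yd, IntegerVector idx,
                               int Hin, int Win) {
  const int Hout = yd[0], Wout = yd[1], C = yd[2], N = yd[3];
  const int S = Hin * Win, So = Hout * Wout;
  NumericVector gx = make4(Hin, Win, C, N);
  const double* gp = gy.begin();
  const int* ip = idx.begin();
  double* o = gx.begin();
  const int P = C * N;
  for (int p = 0; p < P; ++p) {
    const double* g = gp + (size_t)So * p;
    const int* iq = ip + (size_t)So * p;
    double* oq = o + (size_t)S * p;
    for (int s = 0; s < So; ++s) oq[iq[s]] += g[s];
  }
  return gx;
}

// ---------------------------------------------------- channel layer norm ----
// normalizes over the channel axis at every (h, w, n) position
// [[Rcpp::export]]
List cpp_ln_ch_fwd(NumericVector x, IntegerVector xd,
                   NumericVector gamma, NumericVector beta, double eps) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int S = H * W;
  NumericVector y(x.size());
  NumericVector mu((size_t)S * N), istd((size_t)S * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int s = 0; s < S; ++s) {
      const double* xq = xp + s + (size_t)S * C * n;
      double m = 0.0;
      for (int c = 0; c < C; ++c) m += xq[(size_t)S * c];
      m /= C;
      double v = 0.0;
      for (int c = 0; c < C; ++c) {
        const double d = xq[(size_t)S * c] - m;
        v += d * d;
      }
      v /= C;
      const double is = 1.0 / std::sqrt(v + eps);
      mu[s + (size_t)S * n] = m;
      istd[s + (size_t)S * n] = is;
      double* yq = yp + s + (size_t)S * C * n;
      for (int c = 0; c < C; ++c)
        yq[(size_t)S * c] = (xq[(size_t)S * c] - m) * is * gamma[c] + beta[c];
    }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_ln_ch_bwd(NumericVector x, IntegerVector xd, NumericVector gy,
                   NumericVector gamma, NumericVector mu, NumericVector istd) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int S = H * W;
  NumericVector gx(x.size());
  NumericVector ggamma(C), gbeta(C);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* o = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int s = 0; s < S; ++s) {
      const size_t off = s + (size_t)S * C * n;
      const double m = mu[s + (size_t)S * n], is = istd[s + (size_t)S * n];
      double sum_a = 0.0, sum_ax = 0.0;
      for (int c = 0; c < C; ++c) {
        const double xh = (xp[off + (size_t)S * c] - m) * is;
        const double a = gp[off + (size_t)S * c] * gamma[c];
        sum_a += a;
        sum_ax += a * xh;
        ggamma[c] += gp[off + (size_t)S * c] * xh;
        gbeta[c] += gp[off + (size_t)S * c];
      }
      sum_a /= C;
      sum_ax /= C;
      for (int c = 0; c < C; ++c) {
        const double xh = (xp[off + (size_t)S * c] - m) * is;
        const double a = gp[off + (size_t)S * c] * gamma[c];
        o[off + (size_t)S * c] = is * (a - sum_a - xh * sum_ax);
      }
    }
  gx.attr("dim") = x.attr("dim");
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// -------------------------------------------------------------- batchnorm ---
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, IntegerVector xd,
                NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar,
                bool training, double momentum, double eps) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int S = H * W;
  NumericVector y(x.size());
  NumericVector save_mean(C), save_istd(C), rmean_new(C), rvar_new(C);
  const double* xp = x.begin();
  double* yp = y.begin();
  const double cnt = (double)S * N;
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      m = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xq = xp + (size_t)S * (c + (size_t)C * n);
        for (int s = 0; s < S; ++s) m += xq[s];
      }
      m /= cnt;
      v = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xq = xp + (size_t)S * (c + (size_t)C * n);
        for (int s = 0; s < S; ++s) { const double d = xq[s] - m; v += d * d; }
      }
      v /= cnt;
      rmean_new[c] = (1 - momentum) * rmean[c] + momentum * m;
      rvar_new[c] = (1 - momentum) * rvar[c] + momentum * v;
    } else {
      m = rmean[c];
      v = rvar[c];
      rmean_new[c] = rmean[c];
      rvar_new[c] = rvar[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    save_mean[c] = m;
    save_istd[c] = is;
    const double a = gamma[c] * is, b = beta[c] - gamma[c] * is * m;
    for (int n = 0; n < N; ++n) {
      const double* xq = xp + (size_t)S * (c + (size_t)C * n);
      double* yq = yp + (size_t)S * (c + (size_t)C * n);
      for (int s = 0; s < S; ++s) yq[s] = a * xq[s] + b;
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["save_mean"] = save_mean,
                      _["save_istd"] = save_istd, _["rmean"] = rmean_new,
                      _["rvar"] = rvar_new);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, IntegerVector xd, NumericVector gy,
                NumericVector gamma, NumericVector save_mean,
                NumericVector save_istd, bool training) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int S = H * W;
  NumericVector gx(x.size());
  NumericVector ggamma(C), gbeta(C);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* o = gx.begin();
  const double cnt = (double)S * N;
  for (int c = 0; c < C; ++c) {
    const double m = save_mean[c], is = save_istd[c];
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xq = xp + (size_t)S * (c + (size_t)C * n);
      const double* gq = gp + (size_t)S * (c + (size_t)C * n);
      for (int s = 0; s < S; ++s) {
        sg += gq[s];
        sgx += gq[s] * (xq[s] - m) * is;
      }
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    if (training) {
      const double a = gamma[c] * is;
      for (int n = 0; n < N; ++n) {
        const double* xq = xp + (size_t)S * (c + (size_t)C * n);
        const double* gq = gp + (size_t)S * (c + (size_t)C * n);
        double* oq = o + (size_t)S * (c + (size_t)C * n);
        for (int s = 0; s < S; ++s) {
          const double xh = (xq[s] - m) * is;
          oq[s] = a * (gq[s] - sg / cnt - xh * sgx / cnt);
        }
      }
    } else {
      const double a = gamma[c] * is;
      for (int n = 0; n < N; ++n) {
        const double* gq = gp + (size_t)S * (c + (size_t)C * n);
        double* oq = o + (size_t)S * (c + (size_t)C * n);
        for (int s = 0; s < S; ++s) oq[s] = a * gq[s];
      }
    }
  }
  gx.attr("dim") = x.attr("dim");
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---------------------------------------------- nearest-neighbor distances --
// directed nearest-neighbor Euclidean distances from each row of A to set B
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1);
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1);
      const double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ----------------------------------------------------- elementwise ops -----
// [[Rcpp::export]]
NumericVector cpp_gelu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    yp[i] = xp[i] * 0.5 * std::erfc(-xp[i] * M_SQRT1_2);
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_bwd(NumericVector x, NumericVector gy) {
  NumericVector gx(x.size());
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* o = gx.begin();
  const R_xlen_t n = x.size();
  const double inv_sqrt2pi = 0.3989422804014327;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double Phi = 0.5 * std::erfc(-xp[i] * M_SQRT1_2);
    const double phi = inv_sqrt2pi * std::exp(-0.5 * xp[i] * xp[i]);
    o[i] = gp[i] * (Phi + xp[i] * phi);
  }
  gx.attr("dim") = x.attr("dim");
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    yp[i] = xp[i] >= 0 ? xp[i] : slope * xp[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector x, NumericVector gy, double slope) {
  NumericVector gx(x.size());
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* o = gx.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    o[i] = xp[i] >= 0 ? gp[i] : slope * gp[i];
  gx.attr("dim") = x.attr("dim");
  return gx;
}

// per-channel scale: y = x * gamma[c]
// [[Rcpp::export]]
NumericVector cpp_chanscale_fwd(NumericVector x, IntegerVector xd,
                                NumericVector gamma) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int S = H * W;
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double g = gamma[c];
      const double* xq = xp + (size_t)S * (c + (size_t)C * n);
      double* yq = yp + (size_t)S * (c + (size_t)C * n);
      for (int s = 0; s < S; ++s) yq[s] = g * xq[s];
    }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
List cpp_chanscale_bwd(NumericVector x, IntegerVector xd,
                       NumericVector gamma, NumericVector gy) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int S = H * W;
  NumericVector gx(x.size());
  NumericVector ggamma(C);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* o = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double g = gamma[c];
      const size_t off = (size_t)S * (c + (size_t)C * n);
      double acc = 0.0;
      for (int s = 0; s < S; ++s) {
        o[off + s] = g * gp[off + s];
        acc += gp[off + s] * xp[off + s];
      }
      ggamma[c] += acc;
    }
  gx.attr("dim") = x.attr("dim");
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma);
}
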