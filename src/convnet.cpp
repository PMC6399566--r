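// Low-level primitives for the encoder-decoder segmentation networks.
// All tensors are R arrays with dim (H, W, C, N), column-major, double.
// Convolutions are 3x3 stride-1 same-padding (via im2col + GEMM) unless
// noted; the transposed convolution is the 2x2 stride-2 upsampling used in
// the decoder.  Backward passes return gradients with the same shapes as
// their parameters/inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void check_dim4(const NumericVector& x, const char* what) {
  if (Rf_isNull(x.attr("dim")) || IntegerVector(x.attr("dim")).size() != 4)
    stop("%s must be a 4-d (H, W, C, N) array", what);
}

// im2col for a 3x3 same-padded convolution: M is (H*W) x (9*Cin) with
// column index j = dr + 3*dc + 9*ci matching the (3,3,Cin,Cout) layout of
// the weight array.
static void im2col3(const double* x, int H, int W, int Cin, arma::mat& M) {
  const int HW = H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)HW * ci;
    for (int dc = 0; dc < 3; ++dc) {
      for (int dr = 0; dr < 3; ++dr) {
        double* col = M.colptr(dr + 3 * dc + 9 * ci);
        const int roff = dr - 1, coff = dc - 1;
        for (int w = 0; w < W; ++w) {
          const int ws = w + coff;
          double* dst = col + (size_t)H * w;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * ws;
          // rows h: source row h + roff
          if (roff == -1) {
            dst[0] = 0.0;
            std::copy(src, src + H - 1, dst + 1);
          } else if (roff == 0) {
            std::copy(src, src + H, dst);
          } else { // roff == 1
            std::copy(src + 1, src + H, dst);
            dst[H - 1] = 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the columns of GM (same layout as im2col output) back onto
// the padded input gradient.
static void col2im3(const arma::mat& GM, int H, int W, int Cin, double* gx) {
  const int HW = H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    double* gc = gx + (size_t)HW * ci;
    for (int dc = 0; dc < 3; ++dc) {
      for (int dr = 0; dr < 3; ++dr) {
        const double* col = GM.colptr(dr + 3 * dc + 9 * ci);
        const int roff = dr - 1, coff = dc - 1;
        for (int w = 0; w < W; ++w) {
          const int ws = w + coff;
          if (ws < 0 || ws >= W) continue;
          double* dst = gc + (size_t)H * ws;
          const double* src = col + (size_t)H * w;
          const int h0 = std::max(0, -roff), h1 = std::min(H, H - roff);
          for (int h = h0; h < h1; ++h) dst[h + roff] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  check_dim4(x, "x"); check_dim4(w, "w");
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != Cin)
    stop("weight shape mismatch: expected (3,3,%d,Cout)", Cin);
  const int Cout = dw[3], HW = H * W;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)HW * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(w.begin(), 9 * Cin, Cout, false, true);
  arma::mat M(HW, 9 * Cin);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)HW * Cin * n, H, W, Cin, M);
    arma::mat Y(y.begin() + (size_t)HW * Cout * n, HW, Cout, false, true);
    Y = M * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int Cout = dw[3], HW = H * W;
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = dx;
  NumericVector gw(Rf_allocVector(REALSXP, w.size()));
  std::fill(gw.begin(), gw.end(), 0.0);
  gw.attr("dim") = dw;
  NumericVector gb(Cout);
  arma::mat Wm(w.begin(), 9 * Cin, Cout, false, true);
  arma::mat GW(gw.begin(), 9 * Cin, Cout, false, true);
  arma::vec GB(gb.begin(), Cout, false, true);
  arma::mat M(HW, 9 * Cin);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)HW * Cin * n, H, W, Cin, M);
    arma::mat GY(gy.begin() + (size_t)HW * Cout * n, HW, Cout, false, true);
    GW += M.t() * GY;
    GB += arma::sum(GY, 0).t();
    arma::mat GM = GY * Wm.t();
    col2im3(GM, H, W, Cin, gx.begin() + (size_t)HW * Cin * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector nn_conv1x1_fwd(NumericVector x, NumericMatrix w, NumericVector b) {
  check_dim4(x, "x");
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3], HW = H * W;
  if (w.nrow() != Cin) stop("1x1 weight rows must equal input channels");
  const int Cout = w.ncol();
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)HW * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(w.begin(), Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)HW * Cin * n, HW, Cin, false, true);
    arma::mat Y(y.begin() + (size_t)HW * Cout * n, HW, Cout, false, true);
    Y = X * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv1x1_bwd(NumericVector x, NumericMatrix w, NumericVector gy) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3], HW = H * W;
  const int Cout = w.ncol();
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  gx.attr("dim") = dx;
  NumericMatrix gw(Cin, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(w.begin(), Cin, Cout, false, true);
  arma::mat GW(gw.begin(), Cin, Cout, false, true);
  arma::vec GB(gb.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)HW * Cin * n, HW, Cin, false, true);
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)HW * Cout * n, HW, Cout, false, true);
    arma::mat GX(gx.begin() + (size_t)HW * Cin * n, HW, Cin, false, true);
    GX = GY * Wm.t();
    GW += X.t() * GY;
    GB += arma::sum(GY, 0).t();
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x) {
  check_dim4(x, "x");
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("max-pool input dims must be even, got %dx%d", H, W);
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)H2 * W2 * C * N));
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  IntegerVector idx(Rf_allocVector(INTSXP, y.size()));
  idx.attr("dim") = y.attr("dim");
  const double* px = x.begin();
  double* py = y.begin();
  int* pi = idx.begin();
  const size_t planes = (size_t)C * N;
  for (size_t cn = 0; cn < planes; ++cn) {
    const double* xp = px + (size_t)H * W * cn;
    double* yp = py + (size_t)H2 * W2 * cn;
    int* ip = pi + (size_t)H2 * W2 * cn;
    for (int w = 0; w < W2; ++w) {
      for (int h = 0; h < H2; ++h) {
        const int h0 = 2 * h, w0 = 2 * w;
        double best = xp[h0 + H * w0]; int bi = 0;
        double v = xp[h0 + 1 + H * w0];       if (v > best) { best = v; bi = 1; }
        v = xp[h0 + H * (w0 + 1)];            if (v > best) { best = v; bi = 2; }
        v = xp[h0 + 1 + H * (w0 + 1)];        if (v > best) { best = v; bi = 3; }
        yp[h + H2 * w] = best;
        ip[h + H2 * w] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(NumericVector gy, IntegerVector idx, int H, int W) {
  IntegerVector dy = gy.attr("dim");
  const int H2 = dy[0], W2 = dy[1], C = dy[2], N = dy[3];
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* pg = gy.begin();
  const int* pi = idx.begin();
  double* px = gx.begin();
  const size_t planes = (size_t)C * N;
  for (size_t cn = 0; cn < planes; ++cn) {
    const double* gp = pg + (size_t)H2 * W2 * cn;
    const int* ip = pi + (size_t)H2 * W2 * cn;
    double* xp = px + (size_t)H * W * cn;
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const int bi = ip[h + H2 * w];
        const int hh = 2 * h + (bi & 1), ww = 2 * w + (bi >> 1);
        xp[hh + H * ww] += gp[h + H2 * w];
      }
  }
  return gx;
}

// Transposed 2x2 stride-2 convolution. Weight array dim (2,2,Cin,Cout).
// [[Rcpp::export]]
NumericVector nn_upconv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  check_dim4(x, "x"); check_dim4(w, "w");
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  if (dw[0] != 2 || dw[1] != 2 || dw[2] != Cin) stop("upconv weight shape mismatch");
  const int Cout = dw[3], HW = H * W, H2 = 2 * H, W2 = 2 * W;
  // Wm: (Cin) x (4*Cout), column index = (dr + 2*dc) + 4*co
  arma::mat Wm(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dc = 0; dc < 2; ++dc)
        for (int dr = 0; dr < 2; ++dr)
          Wm(ci, dr + 2 * dc + 4 * co) = w[dr + 2 * dc + 4 * ci + 4 * Cin * co];
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)H2 * W2 * Cout * N));
  y.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  double* py = y.begin();
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)HW * Cin * n, HW, Cin, false, true);
    arma::mat T = X * Wm; // (HW) x (4*Cout)
    double* yn = py + (size_t)H2 * W2 * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)H2 * W2 * co;
      for (int dc = 0; dc < 2; ++dc)
        for (int dr = 0; dr < 2; ++dr) {
          const double* tc = T.colptr(dr + 2 * dc + 4 * co);
          for (int ww = 0; ww < W; ++ww)
            for (int hh = 0; hh < H; ++hh)
              yc[(2 * hh + dr) + H2 * (2 * ww + dc)] = tc[hh + H * ww] + b[co];
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_upconv_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int Cout = dw[3], HW = H * W, H2 = 2 * H, W2 = 2 * W;
  arma::mat Wm(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dc = 0; dc < 2; ++dc)
        for (int dr = 0; dr < 2; ++dr)
          Wm(ci, dr + 2 * dc + 4 * co) = w[dr + 2 * dc + 4 * ci + 4 * Cin * co];
  arma::mat GWm(Cin, 4 * Cout, arma::fill::zeros);
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  gx.attr("dim") = dx;
  NumericVector gb(Cout);
  arma::mat GT(HW, 4 * Cout);
  const double* pg = gy.begin();
  for (int n = 0; n < N; ++n) {
    const double* gn = pg + (size_t)H2 * W2 * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gn + (size_t)H2 * W2 * co;
      double bsum = 0.0;
      for (int dc = 0; dc < 2; ++dc)
        for (int dr = 0; dr < 2; ++dr) {
          double* tc = GT.colptr(dr + 2 * dc + 4 * co);
          for (int ww = 0; ww < W; ++ww)
            for (int hh = 0; hh < H; ++hh) {
              const double v = gc[(2 * hh + dr) + H2 * (2 * ww + dc)];
              tc[hh + H * ww] = v;
              bsum += v;
            }
        }
      gb[co] += bsum;
    }
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)HW * Cin * n, HW, Cin, false, true);
    arma::mat GX(gx.begin() + (size_t)HW * Cin * n, HW, Cin, false, true);
    GX = GT * Wm.t();
    GWm += X.t() * GT;
  }
  NumericVector gw(Rf_allocVector(REALSXP, w.size()));
  gw.attr("dim") = dw;
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dc = 0; dc < 2; ++dc)
        for (int dr = 0; dr < 2; ++dr)
          gw[dr + 2 * dc + 4 * ci + 4 * Cin * co] = GWm(ci, dr + 2 * dc + 4 * co);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Batch normalization over (H, W, N) per channel, training mode.
// [[Rcpp::export]]
List nn_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
               double eps) {
  check_dim4(x, "x");
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = dx;
  NumericVector mu(C), invstd(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
    }
    const double mean = s / m;
    double var = s2 / m - mean * mean;
    if (var < 0) var = 0;
    const double inv = 1.0 / std::sqrt(var + eps);
    mu[c] = mean; invstd[c] = inv;
    const double g = gamma[c], bb = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (size_t)C * n);
      double* yp = y.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yp[i] = g * (xp[i] - mean) * inv + bb;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["invstd"] = invstd);
}

// [[Rcpp::export]]
NumericVector nn_bn_infer(NumericVector x, NumericVector gamma, NumericVector beta,
                          NumericVector rmean, NumericVector rvar, double eps) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = dx;
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c], bb = beta[c], mean = rmean[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (size_t)C * n);
      double* yp = y.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yp[i] = g * (xp[i] - mean) * inv + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_bn_bwd(NumericVector x, NumericVector gamma, NumericVector mu,
               NumericVector invstd, NumericVector gy) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  gx.attr("dim") = dx;
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double mean = mu[c], inv = invstd[c], g = gamma[c];
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (size_t)C * n);
      const double* gp = gy.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        sg += gp[i];
        sgx += gp[i] * (xp[i] - mean) * inv;
      }
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    const double c1 = sg / m, c2 = sgx / m;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (size_t)C * n);
      const double* gp = gy.begin() + HW * (c + (size_t)C * n);
      double* op = gx.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        const double xhat = (xp[i] - mean) * inv;
        op[i] = g * inv * (gp[i] - c1 - xhat * c2);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector nn_relu_fwd(NumericVector x) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  const double* px = x.begin(); double* py = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) py[i] = px[i] > 0 ? px[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector nn_relu_bwd(NumericVector x, NumericVector gy) {
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  gx.attr("dim") = x.attr("dim");
  const double* px = x.begin(); const double* pg = gy.begin();
  double* po = gx.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) po[i] = px[i] > 0 ? pg[i] : 0.0;
  return gx;
}
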