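// Minimal batched conv/pool kernels for the small CNN backbone.
// Layout convention: batches are R arrays dim (H, W, C, N), column-major, so
// one image is a contiguous H*W*C block and one channel a contiguous H*W block.
// Conv weights are (k*k*Cin) x Cout matrices; the im2col column index for
// kernel offset (di, dj) and input channel c is di + k*(dj + k*c).
// All convolutions are stride-1 with "same" zero padding (k odd).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_same(const double* x, int H, int W, int C, int k,
                        arma::mat& cols) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * (dj + k * c);
        double* dst = cols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) {
            std::fill(dst + (std::size_t)j * H, dst + (std::size_t)(j + 1) * H, 0.0);
            continue;
          }
          const double* src = xc + (std::size_t)jj * H;
          double* d = dst + (std::size_t)j * H;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - pad;
            d[i] = (ii < 0 || ii >= H) ? 0.0 : src[ii];
          }
        }
      }
    }
  }
}

static void col2im_same(const arma::mat& cols, int H, int W, int C, int k,
                        double* dx) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * (dj + k * c);
        const double* src = cols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          double* d = xc + (std::size_t)jj * H;
          const double* s = src + (std::size_t)j * H;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - pad;
            if (ii >= 0 && ii < H) d[ii] += s[i];
          }
        }
      }
    }
  }
}

static NumericVector make4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, const arma::mat& w, int k) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if ((int)w.n_rows != k * k * C) stop("weight rows do not match k*k*Cin");
  const int Cout = w.n_cols;
  NumericVector out = make4d(H, W, Cout, N);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (std::size_t)n * H * W * C, H, W, C, k, cols);
    arma::mat o = cols * w;  // (H*W) x Cout, memory matches the (H,W,Cout) block
    std::copy(o.memptr(), o.memptr() + o.n_elem,
              out.begin() + (std::size_t)n * H * W * Cout);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, const arma::mat& w, int k, NumericVector dout) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.n_cols;
  IntegerVector dd = dims4(dout);
  if (dd[0] != H || dd[1] != W || dd[2] != Cout || dd[3] != N)
    stop("dout dimensions do not match");
  NumericVector dx = make4d(H, W, C, N);
  arma::mat dw(w.n_rows, w.n_cols, arma::fill::zeros);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (std::size_t)n * H * W * C, H, W, C, k, cols);
    const arma::mat dO((double*)dout.begin() + (std::size_t)n * H * W * Cout,
                       H * W, Cout, false, true);
    dw += cols.t() * dO;
    arma::mat dcols = dO * w.t();
    col2im_same(dcols, H, W, C, k, dx.begin() + (std::size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 2x2 max pooling, stride 2, floor division on odd sizes.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = make4d(Ho, Wo, C, N);
  IntegerVector idx(out.size());  // 0-based linear index into x of each argmax
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  std::size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t base = ((std::size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t bidx = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const std::size_t li = base + (std::size_t)(2 * j + dj) * H + (2 * i + di);
              if (xp[li] > best) { best = xp[li]; bidx = li; }
            }
          }
          op[o] = best;
          ip[o] = (int)bidx;
        }
      }
    }
  }
  out.attr("argmax") = idx;
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector dout, IntegerVector xdim) {
  NumericVector dx = make4d(xdim[0], xdim[1], xdim[2], xdim[3]);
  const double* dp = dout.begin();
  double* xp = dx.begin();
  const int* ip = idx.begin();
  for (R_xlen_t t = 0; t < dout.size(); ++t) xp[ip[t]] += dp[t];
  return dx;
}

// 2x2 average pooling, stride 2 (used as a fixed downsampling stem).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fw(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = make4d(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  std::size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t base = ((std::size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          const std::size_t p = base + (std::size_t)(2 * j) * H + 2 * i;
          op[o] = 0.25 * (xp[p] + xp[p + 1] + xp[p + H] + xp[p + H + 1]);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector out = clone(x);
  double* p = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) if (p[i] < 0) p[i] = 0;
  return out;
}

// Zero dout wherever the forward ReLU output was zero (in place on a copy).
// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector dout, NumericVector act) {
  NumericVector out = clone(dout);
  double* p = out.begin();
  const double* a = act.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) if (a[i] <= 0) p[i] = 0;
  return out;
}

// Sum a (H, W, C, N) gradient over dims 1, 2, 4 -> per-channel bias gradient.
// [[Rcpp::export]]
NumericVector cpp_bias_grad(NumericVector dx) {
  IntegerVector d = dims4(dx);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector out(C);
  const double* p = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      const double* q = p + ((std::size_t)n * C + c) * H * W;
      for (int t = 0; t < H * W; ++t) s += q[t];
      out[c] += s;
    }
  return out;
}
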