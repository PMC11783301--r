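// Low-level layer primitives for the encoder-decoder networks.
// Feature maps travel as H x W x C numeric arrays (arma::cube); conv
// weights as (k*k*Cin) x Cout matrices so that convolution is a single
// im2col matrix product. The im2col matrix computed in the forward pass
// is cached on the tape and reused by the reverse pass. All ops provide
// an exact reverse-mode adjoint.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k) {
  // column ordering: ci * k*k + kj * k + ki  (offset rows fastest)
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int pad = (k - 1) / 2;
  arma::mat out(H * W, k * k * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& sl = x.slice(ci);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ci * k * k + kj * k + ki;
        int dr = ki - pad, dc = kj - pad;
        int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        for (int c = c0; c < c1; ++c) {
          double* dst = out.colptr(col) + (size_t)c * H + r0;
          const double* src = sl.colptr(c + dc) + r0 + dr;
          std::copy(src, src + (r1 - r0), dst);
        }
      }
    }
  }
  return out;
}

static void col2im_add(arma::cube& dx, const arma::mat& dcol, int k) {
  int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  int pad = (k - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    arma::mat& sl = dx.slice(ci);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ci * k * k + kj * k + ki;
        int dr = ki - pad, dc = kj - pad;
        int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        for (int c = c0; c < c1; ++c) {
          double* dst = sl.colptr(c + dc) + r0 + dr;
          const double* src = dcol.colptr(col) + (size_t)c * H + r0;
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
}

// Forward conv; returns the output cube and the im2col matrix for reuse
// in the reverse pass.
// [[Rcpp::export(name = ".conv2d_fw_cpp")]]
List conv2d_fw_cpp(const arma::cube& x, const arma::mat& W, const arma::vec& b, int k) {
  int H = x.n_rows, Wd = x.n_cols;
  int Cout = W.n_cols;
  arma::mat col = im2col(x, k);
  arma::mat y = col * W;
  y.each_row() += b.t();
  arma::cube out(H, Wd, Cout);
  std::copy(y.memptr(), y.memptr() + y.n_elem, out.memptr());
  return List::create(_["y"] = out, _["col"] = col);
}

// Forward conv without returning the im2col matrix (inference path).
// [[Rcpp::export(name = ".conv2d_fwonly_cpp")]]
arma::cube conv2d_fwonly_cpp(const arma::cube& x, const arma::mat& W,
                             const arma::vec& b, int k) {
  int H = x.n_rows, Wd = x.n_cols;
  int Cout = W.n_cols;
  arma::mat col = im2col(x, k);
  arma::mat y = col * W;
  y.each_row() += b.t();
  arma::cube out(H, Wd, Cout);
  std::copy(y.memptr(), y.memptr() + y.n_elem, out.memptr());
  return out;
}

// Reverse conv using the cached im2col matrix.
// [[Rcpp::export(name = ".conv2d_bw_cpp")]]
List conv2d_bw_cpp(const arma::mat& col, const arma::mat& W, const arma::cube& gy,
                   int k, int Cin) {
  int H = gy.n_rows, Wd = gy.n_cols;
  int Cout = W.n_cols;
  arma::mat Gm((double*)gy.memptr(), H * Wd, Cout, false, true);
  arma::mat dW = col.t() * Gm;
  arma::vec db = arma::sum(Gm, 0).t();
  arma::mat dcol = Gm * W.t();
  arma::cube dx(H, Wd, Cin, arma::fill::zeros);
  col2im_add(dx, dcol, k);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled cube and argmax (0-based
// linear index into the input cube) for the reverse pass.
// [[Rcpp::export(name = ".maxpool2_fw_cpp")]]
List maxpool2_fw_cpp(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int H2 = H / 2, W2 = W / 2;
  arma::cube y(H2, W2, C);
  arma::ucube arg(H2, W2, C);
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& X = x.slice(ci);
    for (int c = 0; c < W2; ++c) {
      const double* c0 = X.colptr(2 * c);
      const double* c1 = X.colptr(2 * c + 1);
      for (int r = 0; r < H2; ++r) {
        double v00 = c0[2 * r], v10 = c0[2 * r + 1];
        double v01 = c1[2 * r], v11 = c1[2 * r + 1];
        double best = v00;
        int br = 2 * r, bc = 2 * c;
        if (v10 > best) { best = v10; br = 2 * r + 1; bc = 2 * c; }
        if (v01 > best) { best = v01; br = 2 * r; bc = 2 * c + 1; }
        if (v11 > best) { best = v11; br = 2 * r + 1; bc = 2 * c + 1; }
        y(r, c, ci) = best;
        arg(r, c, ci) = (arma::uword)ci * H * W + (arma::uword)bc * H + br;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_bw_cpp")]]
arma::cube maxpool2_bw_cpp(const arma::cube& gy, const arma::ucube& arg, int H, int W) {
  int C = gy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const double* g = gy.memptr();
  const arma::uword* a = arg.memptr();
  double* d = dx.memptr();
  for (arma::uword i = 0; i < gy.n_elem; ++i) d[a[i]] += g[i];
  return dx;
}

// Per-channel (instance) normalization with affine parameters.
// [[Rcpp::export(name = ".inorm_fw_cpp")]]
List inorm_fw_cpp(const arma::cube& x, const arma::vec& g, const arma::vec& be,
                  double eps) {
  int C = x.n_slices;
  arma::cube y(x.n_rows, x.n_cols, C);
  arma::cube xhat(x.n_rows, x.n_cols, C);
  arma::vec istd(C);
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& X = x.slice(ci);
    double mu = arma::accu(X) / X.n_elem;
    double v = arma::accu(arma::square(X)) / X.n_elem - mu * mu;
    double is = 1.0 / std::sqrt(v + eps);
    istd[ci] = is;
    xhat.slice(ci) = (X - mu) * is;
    y.slice(ci) = xhat.slice(ci) * g[ci] + be[ci];
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export(name = ".inorm_bw_cpp")]]
List inorm_bw_cpp(const arma::cube& xhat, const arma::vec& istd,
                  const arma::vec& g, const arma::cube& gy) {
  int C = gy.n_slices;
  arma::cube dx(gy.n_rows, gy.n_cols, C);
  arma::vec dgamma(C), dbeta(C);
  double n = (double)gy.n_rows * gy.n_cols;
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& dy = gy.slice(ci);
    const arma::mat& xh = xhat.slice(ci);
    dgamma[ci] = arma::accu(dy % xh);
    dbeta[ci] = arma::accu(dy);
    // dxhat = dy * g; dx = istd/n * (n*dxhat - sum(dxhat) - xh*sum(dxhat*xh))
    double s1 = dbeta[ci] * g[ci];
    double s2 = dgamma[ci] * g[ci];
    dx.slice(ci) = (istd[ci] / n) * (n * g[ci] * dy - s1 - xh * s2);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
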