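// Hot numeric kernels: dilated 2-D cross-correlation (forward + backward via
// im2col/col2im), 2x2 max pooling, and BFS connected-component labelling.
// Shape conventions: feature maps are arma::cube (height x width x channels);
// layer weights are a matrix (out_channels x in_channels*q*q) whose column
// index runs fastest over kernel column b, then kernel row a, then in-channel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube pad_cube(const arma::cube& X, int pad) {
  if (pad == 0) return X;
  arma::cube P(X.n_rows + 2 * pad, X.n_cols + 2 * pad, X.n_slices, arma::fill::zeros);
  P.subcube(pad, pad, 0, pad + X.n_rows - 1, pad + X.n_cols - 1, X.n_slices - 1) = X;
  return P;
}

static arma::mat im2col(const arma::cube& P, int q, int stride, int dil,
                        int Ho, int Wo) {
  const int Ci = P.n_slices;
  arma::mat cols(Ci * q * q, (arma::uword)Ho * Wo);
  for (int c = 0; c < Ci; ++c) {
    for (int a = 0; a < q; ++a) {
      for (int b = 0; b < q; ++b) {
        const int row = (c * q + a) * q + b;
        for (int j = 0; j < Wo; ++j) {
          const int pc = j * stride + b * dil;
          for (int i = 0; i < Ho; ++i) {
            cols(row, (arma::uword)j * Ho + i) = P(i * stride + a * dil, pc, c);
          }
        }
      }
    }
  }
  return cols;
}

static void out_shape(const arma::cube& X, int q, int stride, int pad, int dil,
                      int& Ho, int& Wo) {
  const int eff = (q - 1) * dil + 1;
  const int Hp = X.n_rows + 2 * pad, Wp = X.n_cols + 2 * pad;
  if (Hp < eff || Wp < eff)
    stop("kernel (effective extent %d) larger than padded input (%d x %d)", eff, Hp, Wp);
  Ho = (Hp - eff) / stride + 1;
  Wo = (Wp - eff) / stride + 1;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& X, const arma::mat& Wm, const arma::vec& bias,
                      int q, int stride, int pad, int dil) {
  int Ho, Wo;
  out_shape(X, q, stride, pad, dil, Ho, Wo);
  arma::cube P = pad_cube(X, pad);
  arma::mat cols = im2col(P, q, stride, dil, Ho, Wo);
  arma::mat Y = Wm * cols;           // (Co x Ho*Wo), columns in column-major pixel order
  Y.each_col() += bias;
  arma::cube out(Ho, Wo, Wm.n_rows);
  for (arma::uword c = 0; c < Wm.n_rows; ++c)
    out.slice(c) = arma::reshape(Y.row(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube& X, const arma::mat& Wm, const arma::cube& dY,
                         int q, int stride, int pad, int dil) {
  int Ho, Wo;
  out_shape(X, q, stride, pad, dil, Ho, Wo);
  if ((int)dY.n_rows != Ho || (int)dY.n_cols != Wo)
    stop("gradient shape does not match conv output shape");
  arma::cube P = pad_cube(X, pad);
  arma::mat cols = im2col(P, q, stride, dil, Ho, Wo);

  arma::mat dYm(Wm.n_rows, (arma::uword)Ho * Wo);
  for (arma::uword c = 0; c < dY.n_slices; ++c)
    dYm.row(c) = arma::vectorise(dY.slice(c)).t();

  arma::mat dW = dYm * cols.t();
  arma::vec db = arma::sum(dYm, 1);
  arma::mat dcols = Wm.t() * dYm;

  // col2im scatter-add into the padded input gradient
  const int Ci = P.n_slices;
  arma::cube dP(P.n_rows, P.n_cols, Ci, arma::fill::zeros);
  for (int c = 0; c < Ci; ++c) {
    for (int a = 0; a < q; ++a) {
      for (int b = 0; b < q; ++b) {
        const int row = (c * q + a) * q + b;
        for (int j = 0; j < Wo; ++j) {
          const int pc = j * stride + b * dil;
          for (int i = 0; i < Ho; ++i) {
            dP(i * stride + a * dil, pc, c) += dcols(row, (arma::uword)j * Ho + i);
          }
        }
      }
    }
  }
  arma::cube dX = (pad == 0) ? dP
    : arma::cube(dP.subcube(pad, pad, 0, pad + X.n_rows - 1, pad + X.n_cols - 1, Ci - 1));
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2, floor semantics; inputs smaller than the window
// pass through unchanged (argmax = identity) so degenerate 1-px maps survive.
// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  if (H < 2 || W < 2) {
    arma::cube idx(H, W, C);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          idx(i, j, c) = i + j * H;
    return List::create(_["Y"] = X, _["argmax"] = idx, _["identity"] = true);
  }
  const int Ho = (H - 2) / 2 + 1, Wo = (W - 2) / 2 + 1;
  arma::cube Y(Ho, Wo, C), idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int r = 2 * i + di, s = 2 * j + dj;
            const double v = X(r, s, c);
            if (v > best) { best = v; bi = r + s * H; }
          }
        }
        Y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["Y"] = Y, _["argmax"] = idx, _["identity"] = false);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::cube& dY, const arma::cube& argmax,
                                 int H, int W) {
  const int C = dY.n_slices;
  arma::cube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::uword n = dY.n_rows * dY.n_cols;
    for (arma::uword k = 0; k < n; ++k) {
      const int lin = (int)argmax.slice(c)(k);
      dX.slice(c)(lin) += dY.slice(c)(k);
    }
  }
  return dX;
}

// BFS connected-component labelling of a logical matrix; connectivity 4 or 8.
// Labels are 1..n in scan order of first encounter; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  std::vector<int> stack;
  int next = 0;
  const int d4r[] = {-1, 1, 0, 0}, d4c[] = {0, 0, -1, 1};
  const int d8r[] = {-1, 1, 0, 0, -1, -1, 1, 1}, d8c[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = connectivity == 4 ? d4r : d8r;
  const int* dc = connectivity == 4 ? d4c : d8c;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int cur = stack.back(); stack.pop_back();
        const int ci = cur % H, cj = cur / H;
        for (int k = 0; k < connectivity; ++k) {
          const int ni = ci + dr[k], nj = cj + dc[k];
          if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * H);
          }
        }
      }
    }
  }
  return lab;
}
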