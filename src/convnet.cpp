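// Minimal convolution primitives for the FCN engine.
//
// Layout conventions (must match the R side):
//  * feature maps are H x W x C cubes (row index = image row);
//  * conv weights are (k*k*Cin) x Cout matrices, patch element order
//    column = c*k*k + di*k + dj  (channel-major, then kernel row, kernel col);
//  * output pixels are flattened column-major, p = j0*Ho + i0.
//
// A transposed convolution is expressed through the same primitives: its
// forward pass is conv_grad_input of an ordinary convolution, so only three
// kernels are needed (forward, grad wrt input, grad wrt weights).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col(const cube& x, int k, int stride, int pad, int Ho, int Wo) {
  const int C = x.n_slices;
  mat out(static_cast<uword>(Ho) * Wo, static_cast<uword>(k) * k * C);
  for (int c = 0; c < C; ++c) {
    mat padded(x.n_rows + 2 * pad, x.n_cols + 2 * pad, fill::zeros);
    padded.submat(pad, pad, pad + x.n_rows - 1, pad + x.n_cols - 1) = x.slice(c);
    for (int di = 0; di < k; ++di) {
      uvec rows = regspace<uvec>(di, stride, di + (Ho - 1) * stride);
      for (int dj = 0; dj < k; ++dj) {
        uvec cols = regspace<uvec>(dj, stride, dj + (Wo - 1) * stride);
        mat blk = padded.submat(rows, cols);  // Ho x Wo
        out.col(static_cast<uword>(c) * k * k + di * k + dj) = vectorise(blk);
      }
    }
  }
  return out;
}

// adjoint of im2col: scatter-add patch matrix back onto an H x W x C cube
static cube col2im(const mat& M, int k, int stride, int pad,
                   int H, int W, int C, int Ho, int Wo) {
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat padded(H + 2 * pad, W + 2 * pad, fill::zeros);
    for (int di = 0; di < k; ++di) {
      uvec rows = regspace<uvec>(di, stride, di + (Ho - 1) * stride);
      for (int dj = 0; dj < k; ++dj) {
        uvec cols = regspace<uvec>(dj, stride, dj + (Wo - 1) * stride);
        mat blk = reshape(M.col(static_cast<uword>(c) * k * k + di * k + dj), Ho, Wo);
        padded.submat(rows, cols) += blk;
      }
    }
    dx.slice(c) = padded.submat(pad, pad, pad + H - 1, pad + W - 1);
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube nn_conv_fw(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int k, int stride, int pad) {
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = W.n_cols;
  mat P = im2col(x, k, stride, pad, Ho, Wo);
  mat Y = P * W;
  Y.each_row() += b.t();
  cube y(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co) = reshape(Y.col(co), Ho, Wo);
  return y;
}

// gradient of a convolution wrt its input; doubles as the forward pass of a
// transposed convolution with output size Hin x Win
// [[Rcpp::export]]
arma::cube nn_conv_gx(const arma::cube& dy, const arma::mat& W,
                      int k, int stride, int pad, int Hin, int Win) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  const int Cin = W.n_rows / (k * k);
  mat dY(static_cast<uword>(Ho) * Wo, Cout);
  for (int co = 0; co < Cout; ++co) dY.col(co) = vectorise(dy.slice(co));
  mat dP = dY * W.t();
  return col2im(dP, k, stride, pad, Hin, Win, Cin, Ho, Wo);
}

// gradients of a convolution wrt weights and bias
// [[Rcpp::export]]
Rcpp::List nn_conv_gw(const arma::cube& x, const arma::cube& dy,
                      int k, int stride, int pad) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  mat P = im2col(x, k, stride, pad, Ho, Wo);
  mat dY(static_cast<uword>(Ho) * Wo, Cout);
  for (int co = 0; co < Cout; ++co) dY.col(co) = vectorise(dy.slice(co));
  mat dW = P.t() * dY;
  vec db = sum(dY, 0).t();
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
}
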