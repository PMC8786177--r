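// Convolution primitives for the two-phase deblurring networks.
//
// Activations are stored as (channels x positions) matrices whose columns
// enumerate the spatial grid in R's column-major order (first axis fastest).
// Stride-1 same-padded convolution is computed as a sum of small GEMMs over
// kernel offsets ("shift-and-GEMM"): Y = sum_k W_k * shift(X, o_k), which
// avoids materializing the full im2col matrix for 3D volumes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Copy shift(X, off) into B (zero-filled outside). out[n] = in[n + off].
// dims has length 2 or 3.
void shift_into(const arma::mat& X, arma::mat& B, const IntegerVector& dims,
                const int* off) {
  B.zeros();
  const int nx = dims[0], ny = dims[1];
  const int nz = dims.size() == 3 ? dims[2] : 1;
  const int ox = off[0], oy = off[1];
  const int oz = dims.size() == 3 ? off[2] : 0;

  const int x_lo = std::max(0, -ox), x_hi = std::min(nx, nx - ox);  // target range
  if (x_lo >= x_hi) return;
  for (int z = std::max(0, -oz); z < std::min(nz, nz - oz); ++z) {
    for (int y = std::max(0, -oy); y < std::min(ny, ny - oy); ++y) {
      const arma::uword tgt = x_lo + (arma::uword)nx * (y + (arma::uword)ny * z);
      const arma::uword src = (x_lo + ox) + (arma::uword)nx * ((y + oy) + (arma::uword)ny * (z + oz));
      B.cols(tgt, tgt + (x_hi - x_lo) - 1) = X.cols(src, src + (x_hi - x_lo) - 1);
    }
  }
}

}  // namespace

// Forward: Y (Cout x N) = sum_k W.slice(k) * shift(X, offsets[k,])
// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, const arma::cube& W,
                       const IntegerMatrix& offsets, const IntegerVector& dims) {
  const arma::uword N = X.n_cols, Cout = W.n_rows;
  arma::mat Y(Cout, N, arma::fill::zeros);
  arma::mat B(X.n_rows, N);
  int off[3];
  for (int k = 0; k < offsets.nrow(); ++k) {
    for (int a = 0; a < offsets.ncol(); ++a) off[a] = offsets(k, a);
    shift_into(X, B, dims, off);
    Y += W.slice(k) * B;
  }
  return Y;
}

// Gradient w.r.t. input: dX = sum_k W_k^T * shift(dY, -o_k)
// [[Rcpp::export]]
arma::mat cpp_conv_bwd_input(const arma::mat& dY, const arma::cube& W,
                             const IntegerMatrix& offsets, const IntegerVector& dims) {
  const arma::uword N = dY.n_cols, Cin = W.n_cols;
  arma::mat dX(Cin, N, arma::fill::zeros);
  arma::mat B(dY.n_rows, N);
  int off[3];
  for (int k = 0; k < offsets.nrow(); ++k) {
    for (int a = 0; a < offsets.ncol(); ++a) off[a] = -offsets(k, a);
    shift_into(dY, B, dims, off);
    dX += W.slice(k).t() * B;
  }
  return dX;
}

// Gradient w.r.t. weights: dW_k = dY * shift(X, o_k)^T
// [[Rcpp::export]]
arma::cube cpp_conv_bwd_weight(const arma::mat& dY, const arma::mat& X,
                               const IntegerMatrix& offsets, const IntegerVector& dims) {
  arma::cube dW(dY.n_rows, X.n_rows, offsets.nrow(), arma::fill::zeros);
  arma::mat B(X.n_rows, X.n_cols);
  int off[3];
  for (int k = 0; k < offsets.nrow(); ++k) {
    for (int a = 0; a < offsets.ncol(); ++a) off[a] = offsets(k, a);
    shift_into(X, B, dims, off);
    dW.slice(k) = dY * B.t();
  }
  return dW;
}

// ---- strided 2D convolution (PatchGAN critic) -------------------------------
// Output position m = (mx, my) on the decimated grid reads input position
// (mx*stride + ox, my*stride + oy); same zero padding convention as above,
// output dims = ceil(dims / stride).

// [[Rcpp::export]]
arma::mat cpp_sconv_fwd(const arma::mat& X, const arma::cube& W,
                        const IntegerMatrix& offsets, const IntegerVector& dims,
                        int stride) {
  const int nx = dims[0], ny = dims[1];
  const int mx = (nx + stride - 1) / stride, my = (ny + stride - 1) / stride;
  arma::mat Y(W.n_rows, (arma::uword)mx * my, arma::fill::zeros);
  for (int k = 0; k < offsets.nrow(); ++k) {
    const int ox = offsets(k, 0), oy = offsets(k, 1);
    const arma::mat& Wk = W.slice(k);
    for (int jy = 0; jy < my; ++jy) {
      const int sy = jy * stride + oy;
      if (sy < 0 || sy >= ny) continue;
      for (int jx = 0; jx < mx; ++jx) {
        const int sx = jx * stride + ox;
        if (sx < 0 || sx >= nx) continue;
        Y.col(jx + (arma::uword)mx * jy) += Wk * X.col(sx + (arma::uword)nx * sy);
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_sconv_bwd_input(const arma::mat& dY, const arma::cube& W,
                              const IntegerMatrix& offsets, const IntegerVector& dims,
                              int stride) {
  const int nx = dims[0], ny = dims[1];
  const int mx = (nx + stride - 1) / stride, my = (ny + stride - 1) / stride;
  arma::mat dX(W.n_cols, (arma::uword)nx * ny, arma::fill::zeros);
  for (int k = 0; k < offsets.nrow(); ++k) {
    const int ox = offsets(k, 0), oy = offsets(k, 1);
    const arma::mat Wt = W.slice(k).t();
    for (int jy = 0; jy < my; ++jy) {
      const int sy = jy * stride + oy;
      if (sy < 0 || sy >= ny) continue;
      for (int jx = 0; jx < mx; ++jx) {
        const int sx = jx * stride + ox;
        if (sx < 0 || sx >= nx) continue;
        dX.col(sx + (arma::uword)nx * sy) += Wt * dY.col(jx + (arma::uword)mx * jy);
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
arma::cube cpp_sconv_bwd_weight(const arma::mat& dY, const arma::mat& X,
                                const IntegerMatrix& offsets, const IntegerVector& dims,
                                int stride) {
  const int nx = dims[0], ny = dims[1];
  const int mx = (nx + stride - 1) / stride, my = (ny + stride - 1) / stride;
  arma::cube dW(dY.n_rows, X.n_rows, offsets.nrow(), arma::fill::zeros);
  for (int k = 0; k < offsets.nrow(); ++k) {
    const int ox = offsets(k, 0), oy = offsets(k, 1);
    arma::mat& dWk = dW.slice(k);
    for (int jy = 0; jy < my; ++jy) {
      const int sy = jy * stride + oy;
      if (sy < 0 || sy >= ny) continue;
      for (int jx = 0; jx < mx; ++jx) {
        const int sx = jx * stride + ox;
        if (sx < 0 || sx >= nx) continue;
        dWk += dY.col(jx + (arma::uword)mx * jy) * X.col(sx + (arma::uword)nx * sy).t();
      }
    }
  }
  return dW;
}
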