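// Hot path of the U-Net: 3x3 "same" convolution forward/backward via
// im2col + one BLAS gemm, computed in single precision (the customary
// arithmetic for CNN training; all bookkeeping outside these kernels stays
// in R doubles). Tensors arrive as R arrays of dimension (H, W, N, C),
// column-major, channel last.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fvec to_float(const double* x, size_t n) {
  arma::fvec out(n, arma::fill::none);
  float* o = out.memptr();
  for (size_t i = 0; i < n; ++i) o[i] = (float)x[i];
  return out;
}

static arma::fmat im2col3x3(const float* x, int H, int W, int N, int C) {
  const size_t HWN = (size_t)H * W * N;
  arma::fmat X9(HWN, 9 * C, arma::fill::none);
  for (int c = 0; c < C; ++c) {
    const float* xc = x + HWN * c;
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        // X9 column block ordered (ki, kj, c) to match the kernel layout
        float* col = X9.colptr((ki + 1) + 3 * (kj + 1) + 9 * c);
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            int ws = w + kj;
            float* dst = col + (size_t)H * (w + (size_t)W * n);
            if (ws < 0 || ws >= W) {
              std::fill(dst, dst + H, 0.0f);
              continue;
            }
            const float* src = xc + (size_t)H * (ws + (size_t)W * n);
            int h0 = std::max(0, -ki), h1 = std::min(H, H - ki);
            if (h0 > 0) dst[0] = 0.0f;
            std::copy(src + h0 + ki, src + h1 + ki, dst + h0);
            if (h1 < H) dst[H - 1] = 0.0f;
          }
        }
      }
    }
  }
  return X9;
}

// Forward pass. When keep_cols is true the im2col matrix is returned as an
// external pointer so the backward pass does not have to rebuild it.
// [[Rcpp::export(name = ".cpp_conv3x3_forward")]]
List cpp_conv3x3_forward(NumericVector x, NumericVector w, NumericVector b,
                         bool keep_cols = false) {
  IntegerVector dx = x.attr("dim");
  int H = dx[0], W = dx[1], N = dx[2], C = dx[3];
  IntegerVector dw = w.attr("dim");
  int Cout = dw[3];
  const size_t HWN = (size_t)H * W * N;
  arma::fvec xf = to_float(x.begin(), HWN * C);
  arma::fmat* X9 = new arma::fmat(im2col3x3(xf.memptr(), H, W, N, C));
  arma::fmat W9 = arma::conv_to<arma::fmat>::from(
      arma::mat(w.begin(), 9 * C, Cout, false, true));
  arma::fmat Y = (*X9) * W9;
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(
      arma::rowvec(b.begin(), Cout, false, true));
  Y.each_row() += bf;
  NumericVector out(Y.n_elem);
  std::copy(Y.begin(), Y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(H, W, N, Cout);
  if (keep_cols) {
    XPtr<arma::fmat> ptr(X9, true);
    return List::create(_["y"] = out, _["cols"] = ptr);
  }
  delete X9;
  return List::create(_["y"] = out);
}

// [[Rcpp::export(name = ".cpp_conv3x3_backward")]]
List cpp_conv3x3_backward(NumericVector x, NumericVector w, NumericVector dy,
                          SEXP cols = R_NilValue) {
  IntegerVector dx_ = x.attr("dim");
  int H = dx_[0], W = dx_[1], N = dx_[2], C = dx_[3];
  IntegerVector dw_ = w.attr("dim");
  int Cout = dw_[3];
  const size_t HWN = (size_t)H * W * N;

  arma::fmat X9own;
  const arma::fmat* X9p;
  if (cols != R_NilValue) {
    XPtr<arma::fmat> ptr(cols);
    X9p = ptr.get();
  } else {
    arma::fvec xf = to_float(x.begin(), HWN * C);
    X9own = im2col3x3(xf.memptr(), H, W, N, C);
    X9p = &X9own;
  }
  const arma::fmat& X9 = *X9p;
  arma::fvec dyf = to_float(dy.begin(), HWN * Cout);
  arma::fmat dYm(dyf.memptr(), HWN, Cout, false, true);
  arma::fmat W9 = arma::conv_to<arma::fmat>::from(
      arma::mat(w.begin(), 9 * C, Cout, false, true));

  arma::fmat dW9 = X9.t() * dYm;                 // (9C, Cout)
  arma::fmat dX9 = dYm * W9.t();                 // (HWN, 9C)
  arma::frowvec db = arma::sum(dYm, 0);

  // col2im: scatter-add the 9 shifted blocks back onto the input grid
  arma::fvec dxf(HWN * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dxc = dxf.memptr() + HWN * c;
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        const float* col = dX9.colptr((ki + 1) + 3 * (kj + 1) + 9 * c);
        for (int n = 0; n < N; ++n) {
          for (int w2 = 0; w2 < W; ++w2) {
            int ws = w2 + kj;
            if (ws < 0 || ws >= W) continue;
            float* dst = dxc + (size_t)H * (ws + (size_t)W * n);
            const float* src = col + (size_t)H * (w2 + (size_t)W * n);
            int h0 = std::max(0, -ki), h1 = std::min(H, H - ki);
            for (int h = h0; h < h1; ++h) dst[h + ki] += src[h];
          }
        }
      }
    }
  }
  NumericVector dxv(HWN * C);
  std::copy(dxf.begin(), dxf.end(), dxv.begin());
  dxv.attr("dim") = IntegerVector::create(H, W, N, C);
  NumericVector dwv(dW9.n_elem);
  std::copy(dW9.begin(), dW9.end(), dwv.begin());
  dwv.attr("dim") = IntegerVector::create(3, 3, C, Cout);
  NumericVector dbv(db.n_elem);
  std::copy(db.begin(), db.end(), dbv.begin());
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}
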