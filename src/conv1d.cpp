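// Dilated same-padding 1-D convolution primitives for the residual network.
// Feature maps are stored position-major (W x C: one column per channel),
// so the im2col buffer (W x C*K, column index c + C*t) is filled with
// contiguous column copies. Weights are (C*K) x F matrices with the same
// row ordering, i.e. the column-major flattening of an (C, K, F) array.
// One GEMM per convolution; scratch buffers are grow-only and reused
// across calls since reallocating tens of MB per call would dominate.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static std::vector<double>& scratch(int which, size_t n) {
  static std::vector<double> bufs[2];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

// fill M (W x C*K, preallocated) with shifted copies of X's columns
static void im2col(const mat& X, int K, int dilation, mat& M) {
  const int W = X.n_rows;
  const int C = X.n_cols;
  const int center = (K - 1) / 2;
  const double* xp = X.memptr();
  double* mp = M.memptr();
  for (int t = 0; t < K; ++t) {
    const int off = (t - center) * dilation;
    const int lo = std::max(0, -off);
    const int hi = W - 1 - std::max(0, off);
    for (int c = 0; c < C; ++c) {
      double* dst = mp + (size_t)(t * C + c) * W;
      const double* src = xp + (size_t)c * W;
      if (lo > 0) std::memset(dst, 0, (size_t)lo * sizeof(double));
      if (hi >= lo)
        std::memcpy(dst + lo, src + lo + off, (size_t)(hi - lo + 1) * sizeof(double));
      if (hi + 1 < W) std::memset(dst + hi + 1, 0, (size_t)(W - hi - 1) * sizeof(double));
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv1d_forward(const arma::mat& X, const arma::mat& Wmat,
                             const arma::vec& b, int K, int dilation) {
  const int W = X.n_rows;
  const int CK = X.n_cols * K;
  mat M(scratch(0, (size_t)W * CK).data(), W, CK, false, true);
  im2col(X, K, dilation, M);
  mat out = M * Wmat;
  out.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_backward(const arma::mat& X, const arma::mat& Wmat,
                               const arma::mat& G, int K, int dilation) {
  const int W = X.n_rows;
  const int C = X.n_cols;
  const int CK = C * K;
  const int center = (K - 1) / 2;
  mat M(scratch(0, (size_t)W * CK).data(), W, CK, false, true);
  im2col(X, K, dilation, M);
  mat dW = M.t() * G;
  vec db = sum(G, 0).t();
  mat T(scratch(1, (size_t)W * CK).data(), W, CK, false, true);
  T = G * Wmat.t();  // W x (C*K)
  mat dX(W, C, fill::zeros);
  const double* tp = T.memptr();
  double* dxp = dX.memptr();
  for (int t = 0; t < K; ++t) {
    const int off = (t - center) * dilation;
    const int lo = std::max(0, -off);
    const int hi = W - 1 - std::max(0, off);
    if (lo > hi) continue;
    for (int c = 0; c < C; ++c) {
      const double* src = tp + (size_t)(t * C + c) * W + lo;
      double* dst = dxp + (size_t)c * W + lo + off;
      const int n = hi - lo + 1;
      for (int i = 0; i < n; ++i) dst[i] += src[i];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
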