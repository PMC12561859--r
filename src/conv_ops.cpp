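// Compiled kernels for the 3x3 convolution layers: im2col + GEMM forward
// and the exact adjoint backward (col2im). Feature maps are cubes
// [channels, h*w, batch] with column-major pixel index p = col*h + row.
// The nine kernel offsets are enumerated dx in {-1,0,1} (outer) then
// dy in {-1,0,1} (inner); weight matrices are [cout, 9*cin] with the
// offset-k channel block in columns k*cin .. (k+1)*cin - 1.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Training allocates many multi-megabyte temporaries per mini-batch; with
// glibc defaults those are served by mmap and returned immediately, so every
// batch pays page-fault costs again. Raising the mmap/trim thresholds keeps
// freed blocks on the heap for reuse. No-op on non-glibc platforms.
// [[Rcpp::export]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
}

static void im2col3(const mat& Xs, const int h, const int w, mat& P) {
  const int cin = Xs.n_rows;
  P.zeros(9 * cin, h * w);
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      for (int c = 0; c < w; ++c) {
        const int sc = c + dx;
        if (sc < 0 || sc >= w) continue;
        const int rlo = std::max(0, -dy);
        const int rhi = std::min(h, h - dy);
        for (int r = rlo; r < rhi; ++r) {
          std::memcpy(P.colptr(c * h + r) + k * cin,
                      Xs.colptr(sc * h + (r + dy)),
                      cin * sizeof(double));
        }
      }
    }
  }
}

static void col2im3(const mat& dP, const int h, const int w, mat& dXs) {
  const int cin = dXs.n_rows;
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      for (int c = 0; c < w; ++c) {
        const int sc = c + dx;
        if (sc < 0 || sc >= w) continue;
        const int rlo = std::max(0, -dy);
        const int rhi = std::min(h, h - dy);
        for (int r = rlo; r < rhi; ++r) {
          const double* src = dP.colptr(c * h + r) + k * cin;
          double* dst = dXs.colptr(sc * h + (r + dy));
          for (int i = 0; i < cin; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv3_fwd_cpp(const arma::cube& X, const arma::mat& Wbig,
                         const arma::vec& bias, const int h, const int w) {
  const int b = X.n_slices;
  const int cout = Wbig.n_rows;
  cube Y(cout, h * w, b);
  mat P;
  for (int s = 0; s < b; ++s) {
    im2col3(X.slice(s), h, w, P);
    Y.slice(s) = Wbig * P;
    Y.slice(s).each_col() += bias;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd_cpp(const arma::cube& dY, const arma::cube& X,
                         const arma::mat& Wbig, const int h, const int w) {
  const int b = X.n_slices;
  const int cin = X.n_rows;
  const int hw = h * w;
  cube dX(cin, hw, b, fill::zeros);
  mat dW(Wbig.n_rows, Wbig.n_cols, fill::zeros);
  vec db(Wbig.n_rows, fill::zeros);
  mat P(9 * cin, hw), dP(9 * cin, hw);
  for (int s = 0; s < b; ++s) {
    im2col3(X.slice(s), h, w, P);
    const mat& dYs = dY.slice(s);
    dW += dYs * P.t();
    db += sum(dYs, 1);
    dP = Wbig.t() * dYs;
    mat dXs(dX.slice(s).memptr(), cin, hw, false, true);
    col2im3(dP, h, w, dXs);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
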