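// Convolution kernels for the 2D layers.
//
// Activations are (H*W*N) x C matrices (column-major). `idx` is a P x K
// integer matrix mapping each output row and kernel offset to a 1-based
// input row, with 0 denoting zero padding ('same' convolution).
//
// The im2col patch matrix and all GEMMs run in single precision inside
// static workspaces (the deep-learning convention): parameters, inputs and
// returned gradients stay double at the R level. Everything is
// deterministic for fixed inputs.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

extern "C" {
void sgemm_(const char* transa, const char* transb, const int* m,
            const int* n, const int* k, const float* alpha, const float* a,
            const int* lda, const float* b, const int* ldb, const float* beta,
            float* c, const int* ldc);
}

static std::vector<float> g_patches, g_dP, g_A, g_W, g_G, g_Y;

static void to_float(const double* src, std::vector<float>& dst, R_xlen_t n) {
  if ((R_xlen_t)dst.size() < n) dst.resize(n);
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

// im2col of A (float buffer) into g_patches: (P x K*Cin)
static void im2col_f(const std::vector<float>& A, const IntegerMatrix& idx,
                     int P, int Cin) {
  const int K = idx.ncol();
  if ((R_xlen_t)g_patches.size() < (R_xlen_t)P * K * Cin)
    g_patches.resize((R_xlen_t)P * K * Cin);
  for (int o = 0; o < K; ++o) {
    const int* ix = &idx(0, o);
    for (int c = 0; c < Cin; ++c) {
      const float* src = &A[(R_xlen_t)c * P];
      float* dst = &g_patches[((R_xlen_t)o * Cin + c) * P];
      for (int p = 0; p < P; ++p) {
        const int q = ix[p];
        dst[p] = q ? src[q - 1] : 0.0f;
      }
    }
  }
}

// Forward: Y = im2col(A) * W + b.  A: P x Cin, W: (K*Cin) x Cout.
// [[Rcpp::export]]
NumericMatrix conv_fwd_cpp(const NumericMatrix& A, const NumericMatrix& W,
                           const NumericVector& b, const IntegerMatrix& idx) {
  const int P = A.nrow(), Cin = A.ncol(), K = idx.ncol(), Cout = W.ncol();
  const int KC = K * Cin;
  to_float(A.begin(), g_A, (R_xlen_t)P * Cin);
  im2col_f(g_A, idx, P, Cin);
  to_float(W.begin(), g_W, (R_xlen_t)KC * Cout);
  if ((R_xlen_t)g_Y.size() < (R_xlen_t)P * Cout)
    g_Y.resize((R_xlen_t)P * Cout);
  const float one = 1.0f, zero = 0.0f;
  sgemm_("N", "N", &P, &Cout, &KC, &one, g_patches.data(), &P, g_W.data(),
         &KC, &zero, g_Y.data(), &P);
  NumericMatrix Y(P, Cout);
  for (int c = 0; c < Cout; ++c) {
    const float* src = &g_Y[(R_xlen_t)c * P];
    const double bc = b[c];
    double* dst = &Y(0, c);
    for (int p = 0; p < P; ++p) dst[p] = (double)src[p] + bc;
  }
  return Y;
}

// Backward: recomputes the patch matrix from A, then
//   dW = patches^T g,  dP = g W^T,  dA = col2im(dP),  db = colSums(g).
// [[Rcpp::export]]
List conv_bwd_cpp(const NumericMatrix& A, const NumericMatrix& g,
                  const NumericMatrix& W, const IntegerMatrix& idx) {
  const int P = A.nrow(), Cin = A.ncol(), K = idx.ncol(), Cout = W.ncol();
  const int KC = K * Cin;
  to_float(A.begin(), g_A, (R_xlen_t)P * Cin);
  im2col_f(g_A, idx, P, Cin);
  to_float(W.begin(), g_W, (R_xlen_t)KC * Cout);
  to_float(g.begin(), g_G, (R_xlen_t)P * Cout);
  const float one = 1.0f, zero = 0.0f;

  std::vector<float> dWf((R_xlen_t)KC * Cout);
  sgemm_("T", "N", &KC, &Cout, &P, &one, g_patches.data(), &P, g_G.data(), &P,
         &zero, dWf.data(), &KC);
  NumericMatrix dW(KC, Cout);
  for (R_xlen_t i = 0; i < (R_xlen_t)KC * Cout; ++i) dW[i] = dWf[i];

  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    const double* src = &g(0, c);
    double s = 0.0;
    for (int p = 0; p < P; ++p) s += src[p];
    db[c] = s;
  }

  if ((R_xlen_t)g_dP.size() < (R_xlen_t)P * KC)
    g_dP.resize((R_xlen_t)P * KC);
  sgemm_("N", "T", &P, &KC, &Cout, &one, g_G.data(), &P, g_W.data(), &KC,
         &zero, g_dP.data(), &P);

  NumericMatrix dA(P, Cin);  // zero-initialised accumulator
  for (int o = 0; o < K; ++o) {
    const int* ix = &idx(0, o);
    for (int c = 0; c < Cin; ++c) {
      const float* src = &g_dP[((R_xlen_t)o * Cin + c) * P];
      double* dst = &dA(0, c);
      for (int p = 0; p < P; ++p) {
        const int q = ix[p];
        if (q) dst[q - 1] += (double)src[p];
      }
    }
  }
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// Double-precision im2col, used by code paths that need exact patches.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& A, const IntegerMatrix& idx) {
  const int P = A.nrow(), Cin = A.ncol(), K = idx.ncol();
  NumericVector buf(no_init(static_cast<R_xlen_t>(P) * K * Cin));
  buf.attr("dim") = IntegerVector::create(P, K * Cin);
  NumericMatrix out(buf);
  for (int o = 0; o < K; ++o) {
    const int* ix = &idx(0, o);
    for (int c = 0; c < Cin; ++c) {
      const double* src = &A(0, c);
      double* dst = &out(0, o * Cin + c);
      for (int p = 0; p < P; ++p) {
        const int q = ix[p];
        dst[p] = q ? src[q - 1] : 0.0;
      }
    }
  }
  return out;
}
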