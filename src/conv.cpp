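#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <map>
#include <vector>

#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

// Persistent patch-matrix buffers, keyed by layer slot. Convolution cost here
// is dominated by data movement, not flops: the patch matrix for the third
// ECG conv is ~100 MB per batch, so it is built once per forward pass into a
// reused buffer (no R allocation, no zero-fill) and read again by the
// backward pass of the same batch. The forward/backward pair for a given slot
// must not be interleaved with another forward on the same slot — the R
// training loop guarantees this (fwd then bwd per batch, serialized models).
static std::map<int, std::vector<double> > patch_buffers;

static std::vector<double>& get_buffer(std::map<int, std::vector<double> >& reg,
                                       int key, size_t need) {
  std::vector<double>& buf = reg[key];
  if (buf.size() < need) buf.resize(need);
  return buf;
}

static void im2col_fill(const double* ap, double* m, int n, int lenp, int c_in,
                        int k, const int* starts, int out_len) {
  const R_xlen_t nrow = (R_xlen_t)n * out_len;
  for (int c = 0; c < c_in; ++c) {
    const double* apc = ap + (R_xlen_t)c * n * lenp;
    for (int j = 0; j < k; ++j) {
      double* mcol0 = m + ((R_xlen_t)(c * k + j)) * nrow;
      for (int t = 0; t < out_len; ++t) {
        memcpy(mcol0 + (R_xlen_t)t * n, apc + (R_xlen_t)(starts[t] + j) * n,
               n * sizeof(double));
      }
    }
  }
}

// Forward: Z = im2col(Ap) %*% W + b. Ap: (n, lenp, c_in); W: (k*c_in, c_out).
// Returns Z as (n, out_len, c_out). slot identifies the persistent buffer.
// [[Rcpp::export(name = ".conv_fwd_cpp")]]
NumericVector conv_fwd_cpp(NumericVector Ap, int n, int lenp, int c_in, int k,
                           IntegerVector starts, NumericMatrix W,
                           NumericVector bias, int slot) {
  const int out_len = starts.size();
  const int c_out = W.ncol();
  const int kc = k * c_in;
  const R_xlen_t nrow = (R_xlen_t)n * out_len;
  std::vector<double>& M = get_buffer(patch_buffers, slot, (size_t)nrow * kc);
  im2col_fill(Ap.begin(), M.data(), n, lenp, c_in, k, starts.begin(), out_len);
  NumericVector Z((R_xlen_t)nrow * c_out);
  const int m_ = (int)nrow, n_ = c_out, k_ = kc;
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m_, &n_, &k_, &one, M.data(), &m_,
                  W.begin(), &k_, &zero, Z.begin(), &m_ FCONE FCONE);
  double* z = Z.begin();
  for (int o = 0; o < c_out; ++o) {
    const double b = bias[o];
    double* zc = z + (R_xlen_t)o * nrow;
    for (R_xlen_t r = 0; r < nrow; ++r) zc[r] += b;
  }
  Z.attr("dim") = IntegerVector::create(n, out_len, c_out);
  return Z;
}

// Backward: consumes the patch matrix left in `slot` by the matching forward.
// dZ: (n, out_len, c_out). Returns list(dAp (n, lenp, c_in), dW, db).
// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(NumericVector dZ, int n, int lenp, int c_in, int k,
                  IntegerVector starts, NumericMatrix W, int slot) {
  const int out_len = starts.size();
  const int c_out = W.ncol();
  const int kc = k * c_in;
  const R_xlen_t nrow = (R_xlen_t)n * out_len;
  std::vector<double>& M = get_buffer(patch_buffers, slot, (size_t)nrow * kc);
  const double one = 1.0, zero = 0.0;
  // dW = M^T dZ
  NumericMatrix dW(kc, c_out);
  const int m1 = kc, n1 = c_out, k1 = (int)nrow;
  F77_CALL(dgemm)("T", "N", &m1, &n1, &k1, &one, M.data(), &k1,
                  dZ.begin(), &k1, &zero, dW.begin(), &m1 FCONE FCONE);
  // db = column sums of dZ
  NumericVector db(c_out);
  for (int o = 0; o < c_out; ++o) {
    const double* zc = dZ.begin() + (R_xlen_t)o * nrow;
    double s = 0.0;
    for (R_xlen_t r = 0; r < nrow; ++r) s += zc[r];
    db[o] = s;
  }
  // dM = dZ W^T, into a second reused buffer, then scatter-add (col2im)
  std::vector<double>& dM = get_buffer(patch_buffers, -slot - 1,
                                       (size_t)nrow * kc);
  const int m2 = (int)nrow, n2 = kc, k2 = c_out;
  F77_CALL(dgemm)("N", "T", &m2, &n2, &k2, &one, dZ.begin(), &m2,
                  W.begin(), &n2, &zero, dM.data(), &m2 FCONE FCONE);
  NumericVector dAp((R_xlen_t)n * lenp * c_in);
  double* dap = dAp.begin();
  for (int c = 0; c < c_in; ++c) {
    double* dapc = dap + (R_xlen_t)c * n * lenp;
    for (int j = 0; j < k; ++j) {
      const double* mcol0 = dM.data() + ((R_xlen_t)(c * k + j)) * nrow;
      for (int t = 0; t < out_len; ++t) {
        double* dst = dapc + (R_xlen_t)(starts[t] + j) * n;
        const double* src = mcol0 + (R_xlen_t)t * n;
        for (int i = 0; i < n; ++i) dst[i] += src[i];
      }
    }
  }
  dAp.attr("dim") = IntegerVector::create(n, lenp, c_in);
  return List::create(Named("dAp") = dAp, Named("dW") = dW, Named("db") = db);
}

// Release all persistent buffers (called after training runs to cap memory).
// [[Rcpp::export(name = ".conv_buffers_free_cpp")]]
void conv_buffers_free_cpp() {
  patch_buffers.clear();
}
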