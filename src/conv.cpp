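// Compiled kernels for the temporal convolution and mean pooling.
//
// Batch tensors arrive as column-major arrays laid out (n, ch, t, m).
// Viewed as a matrix with n*ch rows and t*m columns, every kernel tap of a
// temporal convolution addresses a contiguous column block, so the im2col
// matrix is assembled from plain contiguous copies (one memcpy per tap and
// input map) and the convolution itself is a single GEMM. Same-padding is
// realized by zero-filling the clipped edge rows instead of padding input.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// im2col: C has n2*t_out rows and m_in*kw columns; column (j-1)*m_in + mi
// holds input map mi shifted by tap j (clipped range zero-filled).
static arma::mat im2col_t(const double* x, int n2, int T, int m_in,
                          int kw, int pl, int t_out) {
  arma::mat C(n2 * (size_t)t_out, m_in * (size_t)kw);
  for (int j = 0; j < kw; ++j) {
    const int shift = j - pl;
    const int a = std::max(0, -shift);
    const int b = std::min(t_out - 1, T - 1 - shift);
    for (int mi = 0; mi < m_in; ++mi) {
      double* dst = C.colptr(j * m_in + mi);
      if (a > 0) std::fill(dst, dst + (size_t)a * n2, 0.0);
      if (b < t_out - 1)
        std::fill(dst + (size_t)(b + 1) * n2, dst + (size_t)t_out * n2, 0.0);
      if (a <= b) {
        const double* src = x + ((size_t)mi * T + a + shift) * n2;
        std::copy(src, src + (size_t)(b - a + 1) * n2,
                  dst + (size_t)a * n2);
      }
    }
  }
  return C;
}

// x: (n, ch, T, m_in); W: (m_in*kw) x m_out rows ordered (j-1)*m_in + mi
// [[Rcpp::export]]
NumericVector conv_t_fwd_cpp(NumericVector x, IntegerVector dims,
                             NumericMatrix W, NumericVector b,
                             int kw, int pl, int t_out) {
  const int n2 = dims[0] * dims[1], T = dims[2], m_in = dims[3];
  const int m_out = W.ncol();
  arma::mat Wm(W.begin(), W.nrow(), m_out, false, true);
  arma::mat C = im2col_t(x.begin(), n2, T, m_in, kw, pl, t_out);
  arma::mat Z = C * Wm;
  for (int mo = 0; mo < m_out; ++mo) Z.col(mo) += b[mo];
  // Z columns are maps; interleave to (n2, t_out*m_out) layout (t fastest)
  NumericVector out((size_t)n2 * t_out * m_out);
  std::copy(Z.begin(), Z.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List conv_t_bwd_cpp(NumericVector dz, NumericVector x, IntegerVector dims,
                    NumericMatrix W, int kw, int pl, int t_out,
                    bool need_input, bool need_params) {
  const int n2 = dims[0] * dims[1], T = dims[2], m_in = dims[3];
  const int m_out = W.ncol();
  arma::mat Wm(W.begin(), W.nrow(), m_out, false, true);
  arma::mat dZ(dz.begin(), n2 * (size_t)t_out, m_out, false, true);
  List out = List::create(Named("dW") = R_NilValue, Named("db") = R_NilValue,
                          Named("dx") = R_NilValue);
  if (need_params) {
    arma::rowvec db = arma::sum(dZ, 0);
    arma::mat dW(m_in * kw, m_out);
    if (m_out >= 4) {                     // GEMM amortizes the im2col build
      arma::mat C = im2col_t(x.begin(), n2, T, m_in, kw, pl, t_out);
      dW = C.t() * dZ;
    } else {                              // few output maps: direct tap dots
      dW.zeros();
      arma::mat Xm(x.begin(), n2, (size_t)T * m_in, false, true);
      for (int j = 0; j < kw; ++j) {
        const int shift = j - pl;
        const int a = std::max(0, -shift);
        const int b = std::min(t_out - 1, T - 1 - shift);
        if (a > b) continue;
        for (int mi = 0; mi < m_in; ++mi) {
          const double* xp = Xm.colptr(mi * T + a + shift);
          const size_t len = (size_t)(b - a + 1) * n2;
          for (int mo = 0; mo < m_out; ++mo) {
            const double* dzp = dZ.colptr(mo) + (size_t)a * n2;
            double s = 0.0;
            for (size_t k = 0; k < len; ++k) s += xp[k] * dzp[k];
            dW(j * m_in + mi, mo) = s;
          }
        }
      }
    }
    out["dW"] = wrap(dW);
    out["db"] = NumericVector(db.begin(), db.end());
  }
  if (need_input) {
    NumericVector dxv((size_t)n2 * T * m_in);
    double* dx = dxv.begin();
    if (m_out >= 4) {
      arma::mat dC = dZ * Wm.t();         // n2*t_out x m_in*kw
      for (int j = 0; j < kw; ++j) {
        const int shift = j - pl;
        const int a = std::max(0, -shift);
        const int b = std::min(t_out - 1, T - 1 - shift);
        if (a > b) continue;
        for (int mi = 0; mi < m_in; ++mi) {
          const double* src = dC.colptr(j * m_in + mi) + (size_t)a * n2;
          double* dst = dx + ((size_t)mi * T + a + shift) * n2;
          const size_t len = (size_t)(b - a + 1) * n2;
          for (size_t k = 0; k < len; ++k) dst[k] += src[k];
        }
      }
    } else {                              // few output maps: direct tap AXPY
      for (int j = 0; j < kw; ++j) {
        const int shift = j - pl;
        const int a = std::max(0, -shift);
        const int b = std::min(t_out - 1, T - 1 - shift);
        if (a > b) continue;
        const size_t len = (size_t)(b - a + 1) * n2;
        for (int mi = 0; mi < m_in; ++mi) {
          double* dst = dx + ((size_t)mi * T + a + shift) * n2;
          for (int mo = 0; mo < m_out; ++mo) {
            const double w = Wm(j * m_in + mi, mo);
            if (w == 0.0) continue;
            const double* dzp = dZ.colptr(mo) + (size_t)a * n2;
            for (size_t k = 0; k < len; ++k) dst[k] += w * dzp[k];
          }
        }
      }
    }
    out["dx"] = dxv;
  }
  return out;
}

// mean pooling along time: windows of `width` at hop `stride`
// [[Rcpp::export]]
NumericVector pool_fwd_cpp(NumericVector x, IntegerVector dims,
                           int width, int stride, int t_out) {
  const int n2 = dims[0] * dims[1], T = dims[2], m = dims[3];
  arma::mat Xm(x.begin(), n2, (size_t)T * m, false, true);
  arma::mat Z(n2, (size_t)t_out * m);
  for (int mi = 0; mi < m; ++mi)
    for (int tp = 0; tp < t_out; ++tp) {
      const int c0 = mi * T + tp * stride;
      Z.col((size_t)mi * t_out + tp) =
        arma::mean(Xm.cols(c0, c0 + width - 1), 1);
    }
  return NumericVector(Z.begin(), Z.end());
}

// [[Rcpp::export]]
NumericVector pool_bwd_cpp(NumericVector dz, IntegerVector dims,
                           int width, int stride, int t_out) {
  const int n2 = dims[0] * dims[1], T = dims[2], m = dims[3];
  arma::mat dZ(dz.begin(), n2, (size_t)t_out * m, false, true);
  arma::mat dX(n2, (size_t)T * m, arma::fill::zeros);
  for (int mi = 0; mi < m; ++mi)
    for (int tp = 0; tp < t_out; ++tp) {
      const arma::vec g = dZ.col((size_t)mi * t_out + tp) / width;
      const int c0 = mi * T + tp * stride;
      for (int j = 0; j < width; ++j) dX.col(c0 + j) += g;
    }
  return NumericVector(dX.begin(), dX.end());
}
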