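#include <Rcpp.h>
using namespace Rcpp;

// Undecimated (a trous) wavelet analysis with circular boundary.
// At level j (1-based) the filters are upsampled by 2^(j-1):
//   a_j[n] = sum_k h0[k] * a_{j-1}[(n - 2^(j-1) k) mod N]
//   d_j[n] = sum_k h1[k] * a_{j-1}[(n - 2^(j-1) k) mod N]
// Every band keeps the input length N. Each tap is applied as one
// circularly shifted vector accumulation (cache-friendly, no per-sample
// modulo).

// [[Rcpp::export]]
List swt_analysis_cpp(NumericVector x, NumericVector h0, NumericVector h1,
                      int levels) {
  const int n = x.size(), nf = h0.size();
  if (levels < 1) stop("levels must be >= 1");
  NumericMatrix details(n, levels);
  std::vector<double> a(x.begin(), x.end()), sa(n), sd(n);
  long step = 1;
  for (int lev = 0; lev < levels; ++lev) {
    std::fill(sa.begin(), sa.end(), 0.0);
    std::fill(sd.begin(), sd.end(), 0.0);
    for (int k = 0; k < nf; ++k) {
      const double c0 = h0[k], c1 = h1[k];
      const int off = (int)((step * k) % n);
      // i in [off, n): source index i - off
      const double *src = a.data();
      for (int i = off; i < n; ++i) {
        const double v = src[i - off];
        sa[i] += c0 * v;
        sd[i] += c1 * v;
      }
      // i in [0, off): source index i - off + n
      for (int i = 0; i < off; ++i) {
        const double v = src[i - off + n];
        sa[i] += c0 * v;
        sd[i] += c1 * v;
      }
    }
    std::copy(sd.begin(), sd.end(), details(_, lev).begin());
    std::copy(sa.begin(), sa.end(), a.begin());
    step *= 2;
  }
  return List::create(_["approx"] = NumericVector(a.begin(), a.end()),
                      _["details"] = details);
}

// Inverse: for conjugate-quadrature (orthogonal) filter pairs the
// undecimated bank satisfies H0(z)H0(1/z) + H1(z)H1(1/z) = 2, so
//   a_{j-1}[n] = 0.5 * sum_k ( h0[k] a_j[(n + 2^(j-1) k) mod N]
//                            + h1[k] d_j[(n + 2^(j-1) k) mod N] )
// reconstructs exactly.

// [[Rcpp::export]]
NumericVector swt_synthesis_cpp(NumericVector approx, NumericMatrix details,
                                NumericVector h0, NumericVector h1) {
  const int n = approx.size(), nf = h0.size();
  const int levels = details.ncol();
  std::vector<double> a(approx.begin(), approx.end()), out(n);
  long step = 1;
  for (int lev = 1; lev < levels; ++lev) step *= 2;
  for (int lev = levels - 1; lev >= 0; --lev) {
    std::fill(out.begin(), out.end(), 0.0);
    const double *d = &details(0, lev);
    for (int k = 0; k < nf; ++k) {
      const double c0 = 0.5 * h0[k], c1 = 0.5 * h1[k];
      const int off = (int)((step * k) % n);
      // out[i] += c0 * a[(i + off) mod n] + c1 * d[(i + off) mod n]
      for (int i = 0; i < n - off; ++i)
        out[i] += c0 * a[i + off] + c1 * d[i + off];
      for (int i = n - off; i < n; ++i)
        out[i] += c0 * a[i + off - n] + c1 * d[i + off - n];
    }
    std::copy(out.begin(), out.end(), a.begin());
    step /= 2;
  }
  return NumericVector(a.begin(), a.end());
}
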