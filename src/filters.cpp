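#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order sections, direct-form II transposed.
// sos: nsec x 6 matrix (b0 b1 b2 a0 a1 a2) with a0 == 1.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  const int ns = sos.nrow();
  const R_xlen_t n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double w1 = 0.0, w2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + w1;
      w1 = b1 * xi - a1 * yi + w2;
      w2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Suppress events closer than min_gap samples to the previous kept event.
// idx must be sorted ascending (1-based sample indices).
// [[Rcpp::export]]
IntegerVector prune_dead_time_cpp(IntegerVector idx, int min_gap) {
  const R_xlen_t n = idx.size();
  if (n == 0) return idx;
  std::vector<int> keep;
  keep.reserve(n);
  int last = idx[0];
  keep.push_back(last);
  for (R_xlen_t i = 1; i < n; ++i) {
    if (idx[i] - last >= min_gap) {
      last = idx[i];
      keep.push_back(last);
    }
  }
  return wrap(keep);
}

// Zero-phase SOS filtering of every row of a matrix, with odd-reflection
// padding of 3*(2*nsections+1) samples (as in filtfilt_sos).
// [[Rcpp::export]]
NumericMatrix sos_filtfilt_mat_cpp(NumericMatrix sos, NumericMatrix x) {
  const int nch = x.nrow();
  const R_xlen_t n = x.ncol();
  const int ns = sos.nrow();
  R_xlen_t padlen = 3 * (2 * ns + 1);
  if (padlen > n - 1) padlen = n - 1;
  const R_xlen_t m = n + 2 * padlen;
  NumericMatrix out(nch, n);
  std::vector<double> buf(m);
  for (int ch = 0; ch < nch; ++ch) {
    for (R_xlen_t i = 0; i < padlen; ++i)
      buf[i] = 2.0 * x(ch, 0) - x(ch, padlen - i);
    for (R_xlen_t i = 0; i < n; ++i) buf[padlen + i] = x(ch, i);
    for (R_xlen_t i = 0; i < padlen; ++i)
      buf[padlen + n + i] = 2.0 * x(ch, n - 1) - x(ch, n - 2 - i);
    // all sections forward, then all sections backward: the same
    // operation order as the vector path, so both paths agree
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      double w1 = 0.0, w2 = 0.0;
      for (R_xlen_t i = 0; i < m; ++i) {
        const double xi = buf[i];
        const double yi = b0 * xi + w1;
        w1 = b1 * xi - a1 * yi + w2;
        w2 = b2 * xi - a2 * yi;
        buf[i] = yi;
      }
    }
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      double w1 = 0.0, w2 = 0.0;
      for (R_xlen_t i = m; i-- > 0;) {
        const double xi = buf[i];
        const double yi = b0 * xi + w1;
        w1 = b1 * xi - a1 * yi + w2;
        w2 = b2 * xi - a2 * yi;
        buf[i] = yi;
      }
    }
    for (R_xlen_t i = 0; i < n; ++i) out(ch, i) = buf[padlen + i];
  }
  return out;
}
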