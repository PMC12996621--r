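#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of the leaky integrate-and-fire encoder for one channel.
// U[n] = U[n-1] + (dt/tau) * (drive[n] - U[n-1]); spike when U >= thr,
// then U <- reset and integration is clamped for the refractory period.
// Returns 1-based sample indices of emitted events.
// [[Rcpp::export]]
IntegerVector lif_spikes_cpp(NumericVector drive, double dt, double tau,
                             double thr, double reset, double refr_s) {
  const R_xlen_t n = drive.size();
  const double k = dt / tau;
  const int refr_samples = (int)std::lround(refr_s / dt);
  std::vector<int> spikes;
  double u = reset;
  int clamp = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (clamp > 0) {
      --clamp;
      continue;
    }
    u += k * (drive[i] - u);
    if (u >= thr) {
      spikes.push_back((int)(i + 1));
      u = reset;
      clamp = refr_samples;
    }
  }
  return wrap(spikes);
}

// Binned LIF encoding for a channels x samples drive matrix.
// Returns an integer matrix of event counts, nbins x channels.
// [[Rcpp::export]]
IntegerMatrix lif_encode_cpp(NumericMatrix drive, double dt, double tau,
                             double thr, double reset, double refr_s,
                             double bin_s) {
  const int nch = drive.nrow();
  const R_xlen_t n = drive.ncol();
  const int nbins = (int)std::floor(n * dt / bin_s + 1e-9);
  const double k = dt / tau;
  const int refr_samples = (int)std::lround(refr_s / dt);
  IntegerMatrix counts(nbins, nch);
  for (int ch = 0; ch < nch; ++ch) {
    double u = reset;
    int clamp = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      if (clamp > 0) {
        --clamp;
        continue;
      }
      u += k * (drive(ch, i) - u);
      if (u >= thr) {
        const int b = (int)(i * dt / bin_s);
        if (b < nbins) counts(b, ch) += 1;
        u = reset;
        clamp = refr_samples;
      }
    }
  }
  return counts;
}
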