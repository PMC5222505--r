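#include <Rcpp.h>

// Naive reference estimator of the response-weighted stimulus covariance
//   C[p,q] = (1/(T-tau)) * sum_{t=tau+1..T} r_t * s[t-i,d1] * s[t-j,d2]
// with p = (d1-1)*L + i, q = (d2-1)*L + j (dim-major, lag-minor layout).
// Each entry is accumulated by its own explicit loop over t, in double
// precision; no symmetry shortcut is taken, so the exact symmetry of the
// result is a property of the arithmetic, not of the code path. This is
// the oracle the vectorized backend is tested against.

// [[Rcpp::export(name = ".rwc_reference_cpp")]]
Rcpp::NumericMatrix rwc_reference_cpp(Rcpp::NumericMatrix s,
                                      Rcpp::NumericVector r,
                                      int tau) {
  const int T = s.nrow();
  const int D = s.ncol();
  const int L = tau + 1;
  const int n = D * L;
  const int nt = T - tau;
  Rcpp::NumericMatrix out(n, n);

  for (int p = 0; p < n; ++p) {
    const int d1 = p / L;
    const int i = p % L;
    for (int q = 0; q < n; ++q) {
      const int d2 = q / L;
      const int j = q % L;
      double acc = 0.0;
      // t is 0-based here; the 1-based formula's t = tau+1..T
      for (int t = tau; t < T; ++t) {
        acc += r[t] * s(t - i, d1) * s(t - j, d2);
      }
      out(p, q) = acc / nt;
    }
  }
  return out;
}
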