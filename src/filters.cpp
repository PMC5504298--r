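#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter along the time axis (columns) of a
// channels x samples matrix, with per-channel initial state zi_scaled[ch][k].
static void df2t_filter(const NumericVector& b, const NumericVector& a,
                        NumericMatrix& x, NumericMatrix& z) {
  int nb = b.size();
  int nch = x.nrow(), ns = x.ncol();
  for (int t = 0; t < ns; ++t) {
    for (int c = 0; c < nch; ++c) {
      double xn = x(c, t);
      double yn = b[0] * xn + z(c, 0);
      for (int k = 1; k < nb - 1; ++k)
        z(c, k - 1) = b[k] * xn - a[k] * yn + z(c, k);
      z(c, nb - 2) = b[nb - 1] * xn - a[nb - 1] * yn;
      x(c, t) = yn;
    }
  }
}

// Zero-phase (forward-backward) filtering of each row of `x` with the IIR
// filter (b, a), a[0] == 1. The signal is extended at both ends by an
// odd-symmetric reflection of length `npad`, and the filter state is
// initialised to the step steady state `zi` scaled by the first sample, so a
// constant input yields the filter's DC response with no edge transient.
// [[Rcpp::export(name = ".filtfilt_mat")]]
NumericMatrix filtfilt_mat(NumericVector b, NumericVector a, NumericVector zi,
                           NumericMatrix x, int npad) {
  int nch = x.nrow(), ns = x.ncol();
  if (ns <= npad)
    stop("filtfilt: signal shorter than padding length");
  int next = ns + 2 * npad;
  NumericMatrix ext(nch, next);
  for (int c = 0; c < nch; ++c) {
    for (int t = 0; t < npad; ++t)
      ext(c, t) = 2.0 * x(c, 0) - x(c, npad - t);
    for (int t = 0; t < ns; ++t)
      ext(c, npad + t) = x(c, t);
    for (int t = 0; t < npad; ++t)
      ext(c, npad + ns + t) = 2.0 * x(c, ns - 1) - x(c, ns - 2 - t);
  }

  int nzi = zi.size();
  NumericMatrix z(nch, nzi);

  // forward pass
  for (int c = 0; c < nch; ++c)
    for (int k = 0; k < nzi; ++k) z(c, k) = zi[k] * ext(c, 0);
  df2t_filter(b, a, ext, z);

  // reverse in place
  for (int c = 0; c < nch; ++c)
    for (int t = 0; t < next / 2; ++t)
      std::swap(ext(c, t), ext(c, next - 1 - t));

  // backward pass
  for (int c = 0; c < nch; ++c)
    for (int k = 0; k < nzi; ++k) z(c, k) = zi[k] * ext(c, 0);
  df2t_filter(b, a, ext, z);

  NumericMatrix out(nch, ns);
  for (int c = 0; c < nch; ++c)
    for (int t = 0; t < ns; ++t)
      out(c, t) = ext(c, next - 1 - npad - t);
  return out;
}

// First-order AR recursion y[t] = x[t] + coef * y[t-1] (stats::filter
// "recursive" equivalent), used for the noise generators.
// [[Rcpp::export(name = ".ar1_filter")]]
NumericVector ar1_filter(NumericVector x, double coef) {
  int n = x.size();
  NumericVector y(n);
  double prev = 0.0;
  for (int t = 0; t < n; ++t) {
    prev = x[t] + coef * prev;
    y[t] = prev;
  }
  return y;
}

// Kellet-style pinking cascade: three staggered AR(1) filters of the same
// white-noise input plus a direct term, approximating a 1/f spectrum.
// [[Rcpp::export(name = ".pink_filter")]]
NumericVector pink_filter(NumericVector w) {
  int n = w.size();
  NumericVector y(n);
  double b0 = 0.0, b1 = 0.0, b2 = 0.0;
  for (int t = 0; t < n; ++t) {
    double x = w[t];
    b0 = 0.99765 * b0 + x * 0.0990460;
    b1 = 0.96300 * b1 + x * 0.2965164;
    b2 = 0.57000 * b2 + x * 1.0526913;
    y[t] = b0 + b1 + b2 + x * 0.1848;
  }
  return y;
}
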