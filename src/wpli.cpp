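// Narrowband wPLI estimation core.
//
// For each center frequency: zero-phase band-pass (squared magnitude
// response of a 4th-order Butterworth band-pass applied in the frequency
// domain), analytic signal, then the weighted phase lag index
//   wPLI_ij = |E[Im(X_ij)]| / E[|Im(X_ij)|],  X_ij = a_i * conj(a_j),
// with the expectation pooled either over all time points and epochs
// (pooling = 0) or over per-epoch time-averaged cross-spectra
// (pooling = 1). Edge samples (a `trim` fraction per side) are discarded
// before pooling.
//
// The filtered analytic signal is reconstructed on the trimmed window by
// a direct inverse DFT over the frequency bins with non-negligible gain
// (the band-pass response falls below GAIN_EPS a few Hz from the center),
// which turns the per-frequency filtering into one small complex matrix
// product instead of a full inverse FFT per channel-epoch.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// bins with band-pass gain below this fraction of the peak (-80 dB) are
// dropped from the inverse-DFT reconstruction
static const double GAIN_EPS = 1e-4;

// squared magnitude response of a 4th-order Butterworth band-pass
// (order-2 low-pass prototype), i.e. the net gain of one forward-backward
// pass of the order-2 design: 1 / (1 + r^4), r = (f^2 - fl*fh)/(f*(fh-fl))
static vec butter_bp_gain(const vec& f, double f0, double bw) {
  const double fl = f0 - bw / 2.0, fh = f0 + bw / 2.0;
  vec g(f.n_elem, fill::zeros);
  for (uword i = 0; i < f.n_elem; ++i) {
    double fa = std::fabs(f[i]);
    if (fa <= 0.0) continue;
    double r = (fa * fa - fl * fh) / (fa * (fh - fl));
    double r2 = r * r;
    g[i] = 1.0 / (1.0 + r2 * r2);
  }
  return g;
}

// x: samples x channels x epochs cube; freqs: center frequencies (Hz)
// returns cube nch x nch x nfreq of wPLI values
// [[Rcpp::export]]
arma::cube wpli_core(const arma::cube& x, const arma::vec& freqs,
                     double bw, double srate, double trim, int pooling) {
  const uword n = x.n_rows, nch = x.n_cols, nep = x.n_slices;
  const uword nf = freqs.n_elem;
  const uword ncol = nch * nep;

  // FFT of every channel-epoch, computed once (column-wise batch FFT)
  mat X(n, ncol);
  for (uword e = 0; e < nep; ++e)
    X.cols(e * nch, (e + 1) * nch - 1) = x.slice(e);
  cx_mat F = fft(X);

  // bin frequencies (two-sided)
  vec fbin(n);
  for (uword k = 0; k < n; ++k)
    fbin[k] = ((k <= n / 2) ? double(k) : double(k) - double(n)) * srate / n;

  // analytic-signal mask: keep DC and Nyquist, double positive bins
  vec mask(n, fill::zeros);
  mask[0] = 1.0;
  if (n % 2 == 0) mask[n / 2] = 1.0;
  for (uword k = 1; k < (n + 1) / 2; ++k) mask[k] = 2.0;

  const uword t0 = (uword)std::floor(n * trim);
  const uword t1 = n - t0;  // exclusive
  const uword T = t1 - t0;

  cube out(nch, nch, nf, fill::zeros);
  mat R(T, nch), I(T, nch);
  const cx_double itwopi(0.0, 2.0 * M_PI / double(n));

  for (uword fi = 0; fi < nf; ++fi) {
    vec gain = butter_bp_gain(fbin, freqs[fi], bw) % mask;
    uvec K = find(gain > GAIN_EPS);

    // E(t, k) = gain_k / n * exp(2*pi*i*K_k*(t0+t)/n): inverse-DFT basis
    // restricted to the retained bins and the trimmed time window
    cx_mat E(T, K.n_elem);
    for (uword k = 0; k < K.n_elem; ++k) {
      double g = gain[K[k]] / double(n);
      for (uword t = 0; t < T; ++t)
        E(t, k) = g * std::exp(itwopi * double(K[k] * (t0 + t) % n));
    }
    cx_mat A = E * F.rows(K);  // T x (nch*nep) filtered analytic signals

    mat sumIm(nch, nch, fill::zeros), sumAbs(nch, nch, fill::zeros);
    for (uword e = 0; e < nep; ++e) {
      for (uword c = 0; c < nch; ++c) {
        const cx_double* a = A.colptr(e * nch + c);
        double* r = R.colptr(c);
        double* im = I.colptr(c);
        for (uword t = 0; t < T; ++t) {
          r[t] = a[t].real();
          im[t] = a[t].imag();
        }
      }
      for (uword i = 0; i < nch; ++i) {
        const double* ri = R.colptr(i);
        const double* ii = I.colptr(i);
        for (uword j = i + 1; j < nch; ++j) {
          const double* rj = R.colptr(j);
          const double* ij = I.colptr(j);
          double sIm = 0.0, sAbs = 0.0;
          for (uword t = 0; t < T; ++t) {
            double v = ii[t] * rj[t] - ri[t] * ij[t];
            sIm += v;
            sAbs += std::fabs(v);
          }
          if (pooling == 0) {
            sumIm(i, j) += sIm;
            sumAbs(i, j) += sAbs;
          } else {
            sumIm(i, j) += sIm / T;
            sumAbs(i, j) += std::fabs(sIm / T);
          }
        }
      }
    }
    for (uword i = 0; i < nch; ++i)
      for (uword j = i + 1; j < nch; ++j) {
        double w = (sumAbs(i, j) > 0.0)
          ? std::fabs(sumIm(i, j)) / sumAbs(i, j) : 0.0;
        out(i, j, fi) = w;
        out(j, i, fi) = w;
      }
  }
  return out;
}

// sliding-window min and max of each row, window length w (samples),
// advancing one sample at a time; returns a list with `min` and `max`
// matrices of nwin = ncol - w + 1 columns. Monotonic-deque algorithm,
// O(samples) per row. Used by the artifact screen.
// [[Rcpp::export]]
Rcpp::List sliding_min_max(const arma::mat& x, int w) {
  const uword nr = x.n_rows, nc = x.n_cols;
  const uword nwin = nc - w + 1;
  mat mn(nr, nwin), mx(nr, nwin);
  rowvec buf(nc);
  std::vector<uword> qmin(nc), qmax(nc);
  for (uword r = 0; r < nr; ++r) {
    buf = x.row(r);  // contiguous copy of the row
    const double* b = buf.memptr();
    size_t h1 = 0, t1 = 0, h2 = 0, t2 = 0;  // [head, tail) index deques
    for (uword i = 0; i < nc; ++i) {
      while (t1 > h1 && b[qmin[t1 - 1]] >= b[i]) --t1;
      qmin[t1++] = i;
      while (t2 > h2 && b[qmax[t2 - 1]] <= b[i]) --t2;
      qmax[t2++] = i;
      if (i + 1 >= (uword)w) {
        uword s = i + 1 - w;  // window start
        if (qmin[h1] < s) ++h1;
        if (qmax[h2] < s) ++h2;
        mn(r, s) = b[qmin[h1]];
        mx(r, s) = b[qmax[h2]];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("min") = mn,
                            Rcpp::Named("max") = mx);
}
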