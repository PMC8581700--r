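// Compiled kernels for the per-frame signal analysis.
//
// All frame start indices passed from R are 0-based. Frames never extend
// past the end of the signal; callers guarantee starts[j] + flen <= length(x).
// FFT-based routines pack two real frames into one complex column (real /
// imaginary parts) so only half the transforms are computed.

#include <RcppArmadillo.h>

using namespace Rcpp;

static inline arma::uword next_pow2(arma::uword n) {
  arma::uword p = 1;
  while (p < n) p <<= 1;
  return p;
}

// Per-frame root-mean-square amplitude.
// [[Rcpp::export]]
NumericVector cpp_frame_rms(NumericVector x, IntegerVector starts, int flen) {
  const int n = starts.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    const int s0 = starts[j];
    for (int k = 0; k < flen; ++k) {
      const double v = x[s0 + k];
      s += v * v;
    }
    out[j] = std::sqrt(s / flen);
  }
  return out;
}

// Linear (non-circular) autocorrelation sums r(0..maxlag) per frame,
// computed with zero-padded FFTs. Returns a (maxlag + 1) x nframes matrix.
// [[Rcpp::export]]
NumericMatrix cpp_frame_acf(NumericVector x, IntegerVector starts, int flen,
                            int maxlag) {
  const int n = starts.size();
  const arma::uword nfft = next_pow2((arma::uword)(flen + maxlag + 1));
  const int npair = (n + 1) / 2;
  NumericMatrix out(maxlag + 1, n);
  if (n == 0) return out;

  arma::cx_mat Z(nfft, npair, arma::fill::zeros);
  for (int j = 0; j < npair; ++j) {
    const int f1 = 2 * j, f2 = 2 * j + 1;
    const int s1 = starts[f1];
    if (f2 < n) {
      const int s2 = starts[f2];
      for (int k = 0; k < flen; ++k)
        Z(k, j) = std::complex<double>(x[s1 + k], x[s2 + k]);
    } else {
      for (int k = 0; k < flen; ++k)
        Z(k, j) = std::complex<double>(x[s1 + k], 0.0);
    }
  }
  Z = arma::fft(Z);

  // Separate the two packed real spectra; repack their power spectra as
  // real/imaginary parts so one inverse transform yields both acfs.
  arma::cx_mat P(nfft, npair);
  for (int j = 0; j < npair; ++j) {
    for (arma::uword k = 0; k < nfft; ++k) {
      const arma::uword k2 = (nfft - k) % nfft;
      const std::complex<double> zk = Z(k, j), zc = std::conj(Z(k2, j));
      const std::complex<double> A = 0.5 * (zk + zc);
      const std::complex<double> D = zk - zc;  // = 2i * B
      const std::complex<double> B(0.5 * D.imag(), -0.5 * D.real());
      P(k, j) = std::complex<double>(std::norm(A), std::norm(B));
    }
  }
  P = arma::ifft(P);
  for (int j = 0; j < npair; ++j) {
    const int f1 = 2 * j, f2 = 2 * j + 1;
    for (int t = 0; t <= maxlag; ++t) {
      out(t, f1) = P(t, j).real();
      if (f2 < n) out(t, f2) = P(t, j).imag();
    }
  }
  return out;
}

// Windowed power spectrum per frame: (nfft/2 + 1) x nframes.
// [[Rcpp::export]]
NumericMatrix cpp_frame_powspec(NumericVector x, IntegerVector starts,
                                int flen, NumericVector window, int nfft) {
  const int n = starts.size();
  const int nbin = nfft / 2 + 1;
  NumericMatrix out(nbin, n);
  if (n == 0) return out;
  const int npair = (n + 1) / 2;
  arma::cx_mat Z(nfft, npair, arma::fill::zeros);
  for (int j = 0; j < npair; ++j) {
    const int f1 = 2 * j, f2 = 2 * j + 1;
    const int s1 = starts[f1];
    if (f2 < n) {
      const int s2 = starts[f2];
      for (int k = 0; k < flen; ++k)
        Z(k, j) = std::complex<double>(x[s1 + k] * window[k],
                                       x[s2 + k] * window[k]);
    } else {
      for (int k = 0; k < flen; ++k)
        Z(k, j) = std::complex<double>(x[s1 + k] * window[k], 0.0);
    }
  }
  Z = arma::fft(Z);
  for (int j = 0; j < npair; ++j) {
    const int f1 = 2 * j, f2 = 2 * j + 1;
    for (int k = 0; k < nbin; ++k) {
      const arma::uword k2 = (nfft - k) % nfft;
      const std::complex<double> zk = Z(k, j), zc = std::conj(Z(k2, j));
      const std::complex<double> A = 0.5 * (zk + zc);
      const std::complex<double> D = zk - zc;
      const std::complex<double> B(0.5 * D.imag(), -0.5 * D.real());
      out(k, f1) = std::norm(A);
      if (f2 < n) out(k, f2) = std::norm(B);
    }
  }
  return out;
}

// Autocorrelation peak search for pitch tracking. `acf` is the matrix from
// cpp_frame_acf. The normalized curve r(t) = acf(t)/acf(0) is corrected for
// the rectangular-window taper (division by 1 - t/flen). Among local maxima
// in [lag_min, lag_max] reaching 85% of the global maximum, the smallest lag
// wins (guards against octave errors); the peak is refined by parabolic
// interpolation. Returns nframes x 2: interpolated lag (samples; NaN if no
// peak) and peak height.
// [[Rcpp::export]]
NumericMatrix cpp_f0_peaks(NumericMatrix acf, int lag_min, int lag_max,
                           int flen) {
  const int n = acf.ncol();
  const int maxlag = acf.nrow() - 1;
  NumericMatrix out(n, 2);
  const int hi = std::min(lag_max, maxlag - 1);
  for (int j = 0; j < n; ++j) {
    out(j, 0) = NA_REAL;
    out(j, 1) = 0.0;
    const double r0 = acf(0, j);
    if (!(r0 > 0) || lag_min < 2 || hi <= lag_min) continue;
    // normalized, taper-corrected curve over [lag_min - 1, hi + 1]
    double best_val = -1e300;
    for (int t = lag_min; t <= hi; ++t) {
      const double rt = acf(t, j) / r0 / (1.0 - (double)t / flen);
      if (rt > best_val) best_val = rt;
    }
    if (!(best_val > 0)) continue;
    int pick = -1;
    double rm1 = 0, rp0 = 0, rp1 = 0;
    for (int t = lag_min; t <= hi; ++t) {
      const double a = acf(t - 1, j) / r0 / (1.0 - (double)(t - 1) / flen);
      const double b = acf(t, j) / r0 / (1.0 - (double)t / flen);
      const double c = acf(t + 1, j) / r0 / (1.0 - (double)(t + 1) / flen);
      if (b >= a && b >= c && b >= 0.85 * best_val) {
        pick = t; rm1 = a; rp0 = b; rp1 = c;
        break;
      }
    }
    if (pick < 0) continue;
    double lag = pick, height = rp0;
    const double denom = rm1 - 2.0 * rp0 + rp1;
    if (denom < 0) {
      const double delta = 0.5 * (rm1 - rp1) / denom;
      if (std::fabs(delta) <= 1.0) {
        lag = pick + delta;
        height = rp0 - 0.25 * (rm1 - rp1) * delta;
      }
    }
    if (height > 0.999999) height = 0.999999;
    out(j, 0) = lag;
    out(j, 1) = height;
  }
  return out;
}

static void levinson_durbin(const double* r, int order, double* a) {
  // Solves the LPC normal equations; a[0..order] with a[0] = 1.
  a[0] = 1.0;
  for (int i = 1; i <= order; ++i) a[i] = 0.0;
  double err = r[0];
  std::vector<double> tmp(order + 1);
  for (int i = 1; i <= order; ++i) {
    double acc = r[i];
    for (int j = 1; j < i; ++j) acc += a[j] * r[i - j];
    const double k = (err > 0) ? (-acc / err) : 0.0;
    for (int j = 0; j <= i; ++j) tmp[j] = a[j];
    for (int j = 1; j < i; ++j) a[j] = tmp[j] + k * tmp[i - j];
    a[i] = k;
    err *= (1.0 - k * k);
    if (err <= 0) break;
  }
}

// Per-frame formant candidates by the autocorrelation method of linear
// prediction: window, autocorrelate, Levinson recursion, polynomial roots.
// Roots with positive frequency, fmin < f < fs/2 - 50 and bandwidth < max_bw
// qualify; frames with fewer than three qualifying roots yield NaN. Returns
// nframes x 6: F1 F2 F3 B1 B2 B3 (Hz).
// [[Rcpp::export]]
NumericMatrix cpp_lpc_formants(NumericVector x, IntegerVector starts,
                               int flen, NumericVector window, int order,
                               double fs, double max_bw, double fmin) {
  const int n = starts.size();
  NumericMatrix out(n, 6);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> w(flen), r(order + 1), a(order + 1);
  arma::vec coef(order + 1);
  for (int j = 0; j < n; ++j) {
    const int s0 = starts[j];
    for (int k = 0; k < flen; ++k) w[k] = x[s0 + k] * window[k];
    for (int t = 0; t <= order; ++t) {
      double s = 0;
      for (int k = 0; k < flen - t; ++k) s += w[k] * w[k + t];
      r[t] = s;
    }
    if (!(r[0] > 1e-20)) continue;
    r[0] *= 1.0 + 1e-9;
    levinson_durbin(r.data(), order, a.data());
    for (int t = 0; t <= order; ++t) coef[t] = a[t];
    arma::cx_vec rt;
    try {
      rt = arma::roots(coef);
    } catch (...) {
      continue;
    }
    std::vector<std::pair<double, double>> cand;  // (freq, bw)
    for (arma::uword i = 0; i < rt.n_elem; ++i) {
      const double im = rt[i].imag();
      if (im <= 1e-9) continue;
      const double f = std::atan2(im, rt[i].real()) * fs / (2.0 * M_PI);
      const double m = std::abs(rt[i]);
      if (m <= 0 || m >= 1.0) continue;
      const double bw = -std::log(m) * fs / M_PI;
      if (f > fmin && f < fs / 2.0 - 50.0 && bw < max_bw)
        cand.push_back(std::make_pair(f, bw));
    }
    if (cand.size() < 3) continue;
    std::sort(cand.begin(), cand.end());
    for (int i = 0; i < 3; ++i) {
      out(j, i) = cand[i].first;
      out(j, i + 3) = cand[i].second;
    }
  }
  return out;
}

// Normalized cross-correlation between the window starting at m and the
// window starting at the (possibly fractional) lag m + tau, both of length
// L. Fractional sample values are reconstructed with a 21-tap Hann-windowed
// sinc interpolator, accurate for signals band-limited below ~0.9 Nyquist.
static double frac_cc(const double* x, int n, int m, double tau, int L,
                      double e1) {
  const int HW = 10;
  const double ti = m + tau;
  const int t0 = (int)std::floor(ti);
  const double frac = ti - t0;
  double c = 0, e2 = 0;
  if (frac < 1e-9) {  // integer lag: direct
    if (t0 < 0 || t0 + L > n) return -1;
    for (int k = 0; k < L; ++k) {
      const double v = x[t0 + k];
      c += x[m + k] * v;
      e2 += v * v;
    }
  } else {
    double w[2 * HW];  // interpolation kernel for this fraction
    for (int j = 0; j < 2 * HW; ++j) {
      const double u = frac - (j - HW + 1);  // distance to tap
      const double s = std::sin(M_PI * u) / (M_PI * u);
      w[j] = s * (0.5 + 0.5 * std::cos(M_PI * u / HW));
    }
    if (t0 - HW + 1 < 0 || t0 + L + HW > n) return -1;
    for (int k = 0; k < L; ++k) {
      double v = 0;
      const double* base = x + t0 + k - HW + 1;
      for (int j = 0; j < 2 * HW; ++j) v += w[j] * base[j];
      c += x[m + k] * v;
      e2 += v * v;
    }
  }
  if (!(e1 > 0) || !(e2 > 0)) return -1;
  return c / std::sqrt(e1 * e2);
}

// Glottal-cycle tracking within one voiced region. Coarse cycle marks are
// picked as waveform extrema one expected period apart; each period is then
// refined to sub-sample precision by maximizing the normalized
// cross-correlation between consecutive cycle-length windows (waveform
// matching with band-limited fractional-delay interpolation), which also
// yields a per-cycle harmonicity coefficient. Returns marks (0-based
// sample indices), periods (samples, refined), amps (per-cycle RMS over
// the coarse period) and ccs (normalized cross-correlation at the refined
// lag).
// [[Rcpp::export]]
List cpp_track_pulses(NumericVector x, double texp) {
  const int n = x.size();
  const int T = (int)std::round(texp);
  std::vector<int> marks;
  std::vector<double> periods, amps, ccs, tauvar;
  if (n >= 2 * T && T >= 8) {
    const int w1 = std::min((int)std::ceil(1.5 * texp), n);
    int p = 0;
    double best = -1;
    for (int k = 0; k < w1; ++k) {
      const double v = std::fabs(x[k]);
      if (v > best) { best = v; p = k; }
    }
    const double pol = (x[p] >= 0) ? 1.0 : -1.0;
    marks.push_back(p);
    while (true) {
      const int lo = p + (int)std::floor(0.70 * texp);
      const int hi = std::min(p + (int)std::ceil(1.35 * texp), n);
      if (hi - lo < 3 || lo >= n) break;
      int q = lo;
      double bv = -1e300;
      for (int k = lo; k < hi; ++k) {
        const double v = pol * x[k];
        if (v > bv) { bv = v; q = k; }
      }
      marks.push_back(q);
      p = q;
    }
    const int K = (int)marks.size();
    const int L0 = (int)std::round(0.8 * texp);
    const double* xp = x.begin();
    for (int i = 0; i + 1 < K; ++i) {
      const int m = marks[i];
      const int d = marks[i + 1] - m;
      const int L = std::min(L0, n - (m + d + 18));
      if (L < 8 || d < 8 || m < 12) continue;
      double e1 = 0;
      for (int k = 0; k < L; ++k) e1 += x[m + k] * x[m + k];
      // integer-lag scan
      double rv[11];
      int bi = -1;
      double bvv = -1e300;
      for (int t = 0; t < 11; ++t) {
        const int tau = d - 5 + t;
        rv[t] = (tau >= 6) ? frac_cc(xp, n, m, (double)tau, L, e1) : -1;
        if (rv[t] > bvv) { bvv = rv[t]; bi = t; }
      }
      if (bi < 0 || bvv <= -1) continue;
      double tau0 = d - 5 + bi;
      if (bi > 0 && bi < 10 && rv[bi - 1] > -1 && rv[bi + 1] > -1) {
        const double den = rv[bi - 1] - 2 * rv[bi] + rv[bi + 1];
        if (den < 0) {
          const double delta = 0.5 * (rv[bi - 1] - rv[bi + 1]) / den;
          if (std::fabs(delta) <= 1.0) tau0 += delta;
        }
      }
      // fractional refinement: quarter-sample scan, then parabola
      double fr[5], tau_hat = tau0, r_hat = -1, curv = NA_REAL;
      int fb = -1;
      for (int t = 0; t < 5; ++t) {
        fr[t] = frac_cc(xp, n, m, tau0 + 0.25 * (t - 2), L, e1);
        if (fr[t] > r_hat) { r_hat = fr[t]; fb = t; }
      }
      if (fb >= 0) tau_hat = tau0 + 0.25 * (fb - 2);
      if (fb > 0 && fb < 4 && fr[fb - 1] > -1 && fr[fb + 1] > -1) {
        const double den = fr[fb - 1] - 2 * fr[fb] + fr[fb + 1];
        if (den < 0) {
          curv = -den / 0.0625;  // -r''(tau) at the peak, per sample^2
          double delta = 0.125 * (fr[fb - 1] - fr[fb + 1]) / den;
          if (delta > 0.2) delta = 0.2;
          if (delta < -0.2) delta = -0.2;
          const double rf = frac_cc(xp, n, m, tau_hat + delta, L, e1);
          if (rf > r_hat) { r_hat = rf; tau_hat += delta; }
        }
      }
      if (!(r_hat > -1)) continue;
      // lag-estimation noise variance (samples^2), generalized
      // cross-correlation result: (1 - r^2) / (L r^2 c2)
      double tv = NA_REAL;
      if (R_finite(curv) && curv > 0 && r_hat > 0.1) {
        tv = (1 - r_hat * r_hat) / (L * r_hat * r_hat * curv);
      }
      double ea = 0;
      for (int k = 0; k < d && m + k < n; ++k) ea += x[m + k] * x[m + k];
      periods.push_back(tau_hat);
      amps.push_back(std::sqrt(ea / d));
      tauvar.push_back(tv);
      ccs.push_back(std::min(std::max(r_hat, 0.0), 0.999999));
    }
  }
  return List::create(_["marks"] = wrap(marks), _["periods"] = wrap(periods),
                      _["amps"] = wrap(amps), _["ccs"] = wrap(ccs),
                      _["tauvar"] = wrap(tauvar));
}

// Cascade of two-pole resonator sections applied in one pass:
// y_j(t) = b0_j x(t) + a1_j y_j(t-1) + a2_j y_j(t-2).
// [[Rcpp::export]]
NumericVector cpp_biquad_cascade(NumericVector b0, NumericVector a1,
                                 NumericVector a2, NumericVector x) {
  const int ns = b0.size();
  const int n = x.size();
  NumericVector y(n);
  std::vector<double> z1(ns, 0.0), z2(ns, 0.0);
  for (int t = 0; t < n; ++t) {
    double v = x[t];
    for (int j = 0; j < ns; ++j) {
      const double out = b0[j] * v + a1[j] * z1[j] + a2[j] * z2[j];
      z2[j] = z1[j];
      z1[j] = out;
      v = out;
    }
    y[t] = v;
  }
  return y;
}

// Direct-form II transposed IIR filter y = filter(b, a, x), a[0] = 1.
// [[Rcpp::export]]
NumericVector cpp_iir(NumericVector b, NumericVector a, NumericVector x) {
  const int n = x.size();
  const int nb = b.size(), na = a.size();
  const int ns = std::max(nb, na) - 1;
  std::vector<double> z(ns + 1, 0.0), bb(ns + 1, 0.0), aa(ns + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = bb[0] * xt + z[0];
    for (int i = 0; i < ns; ++i)
      z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
    y[t] = yt;
  }
  return y;
}

// Sum of band-limited excitation pulses at sub-sample positions pos_i.
// Each pulse is a Hann-windowed sinc with the given relative cutoff
// (fraction of Nyquist), L2-normalized and scaled by gain_i. Band-limited
// pulses are shift-invariant: shape, spectrum and energy are independent
// of the fractional position, so planted cycle gains survive sampling
// exactly.
// [[Rcpp::export]]
NumericVector cpp_bl_pulses(int n, NumericVector pos, NumericVector gain,
                            double cutoff) {
  NumericVector out(n);
  const int HW = 16;
  double v[2 * HW + 1];
  for (int i = 0; i < pos.size(); ++i) {
    const double c = pos[i];
    const int k0 = (int)std::ceil(c) - HW;
    double e = 0;
    for (int j = 0; j <= 2 * HW; ++j) {
      const double u = (k0 + j) - c;
      const double au = std::fabs(u);
      double s;
      if (au < 1e-9) s = cutoff;
      else s = std::sin(M_PI * cutoff * u) / (M_PI * u);
      if (au < HW) s *= 0.5 + 0.5 * std::cos(M_PI * u / HW);
      else s = 0;
      v[j] = s;
      e += s * s;
    }
    if (e <= 0) continue;
    const double sc = gain[i] / std::sqrt(e);
    for (int j = 0; j <= 2 * HW; ++j) {
      const int k = k0 + j;
      if (k >= 0 && k < n) out[k] += sc * v[j];
    }
  }
  return out;
}
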