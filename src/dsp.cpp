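// Time-series kernels used by the preprocessing chain.
//
// Both routines operate column-wise on a [time x series] matrix so a whole
// run (all channels x wavelengths) is processed in one call.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// Direct-form II transposed IIR filter, single pass, in place on a vector.
static void iir_pass(std::vector<double>& x, const std::vector<double>& b,
                     const std::vector<double>& a) {
  const int n = static_cast<int>(x.size());
  const int p = static_cast<int>(b.size());
  std::vector<double> z(p, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 1; j < p; ++j)
      z[j - 1] = b[j] * xi + z[j] - a[j] * yi;
    x[i] = yi;
  }
}

// Zero-phase filtering: odd-reflection padding at both ends, forward pass,
// time reversal, second pass, reversal, trim.  `padlen` samples of padding
// absorb the filter start-up transient.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_mat(const NumericMatrix& x, const NumericVector& b,
                               const NumericVector& a, int padlen) {
  const int n = x.nrow(), m = x.ncol();
  if (n <= 1) return clone(x);
  if (padlen >= n) padlen = n - 1;
  if (padlen < 0) padlen = 0;
  const int p = static_cast<int>(b.size());
  if (static_cast<int>(a.size()) != p) stop("b and a must have equal length");
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  if (av[0] != 1.0) {
    for (int j = 0; j < p; ++j) { bv[j] /= av[0]; }
    for (int j = p - 1; j >= 0; --j) av[j] /= av[0];
  }

  NumericMatrix out(n, m);
  const int ext = n + 2 * padlen;
  std::vector<double> buf(ext);
  for (int c = 0; c < m; ++c) {
    // odd reflection: 2*x[0] - x[k]
    for (int i = 0; i < padlen; ++i)
      buf[i] = 2.0 * x(0, c) - x(padlen - i, c);
    for (int i = 0; i < n; ++i) buf[padlen + i] = x(i, c);
    for (int i = 0; i < padlen; ++i)
      buf[padlen + n + i] = 2.0 * x(n - 1, c) - x(n - 2 - i, c);

    iir_pass(buf, bv, av);
    std::reverse(buf.begin(), buf.end());
    iir_pass(buf, bv, av);
    std::reverse(buf.begin(), buf.end());

    for (int i = 0; i < n; ++i) out(i, c) = buf[padlen + i];
  }
  return out;
}

// Anti-aliased arbitrary-ratio resampler: each output sample is a
// Blackman-windowed-sinc interpolation of the input evaluated at the output
// instant, with the kernel cutoff below the output Nyquist rate.  Kernel
// weights are renormalised per output sample so a constant series is
// reproduced exactly, including at the edges.
// [[Rcpp::export]]
NumericMatrix cpp_resample_mat(const NumericMatrix& x, double fs_in,
                               double fs_out, double cutoff_hz,
                               double transition_hz) {
  const int n = x.nrow(), m = x.ncol();
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive");
  const double duration = n / fs_in;
  const int n_out = static_cast<int>(std::lround(duration * fs_out));
  const double nu = cutoff_hz / fs_in;              // cycles per input sample
  const double dnu = transition_hz / fs_in;
  const int L = std::max(8, static_cast<int>(std::ceil(2.0 / dnu)));

  NumericMatrix out(n_out, m);
  // precompute the (normalised) kernel of every output sample once
  std::vector<std::vector<double>> wj(n_out);
  std::vector<int> kj0(n_out);
  for (int j = 0; j < n_out; ++j) {
    const double t = j * fs_in / fs_out;  // output instant in input samples
    const int k0 = std::max(0, static_cast<int>(std::ceil(t - L)));
    const int k1 = std::min(n - 1, static_cast<int>(std::floor(t + L)));
    kj0[j] = k0;
    std::vector<double>& w = wj[j];
    w.resize(k1 - k0 + 1);
    double wsum = 0.0;
    for (int k = k0; k <= k1; ++k) {
      const double u = k - t;
      double s = (u == 0.0) ? 2.0 * nu
                            : std::sin(2.0 * M_PI * nu * u) / (M_PI * u);
      const double q = u / L;  // Blackman window on [-1, 1]
      s *= 0.42 + 0.5 * std::cos(M_PI * q) + 0.08 * std::cos(2.0 * M_PI * q);
      w[k - k0] = s;
      wsum += s;
    }
    if (wsum == 0.0) wsum = 1.0;
    for (auto& v : w) v /= wsum;
  }
  for (int c = 0; c < m; ++c) {
    const double* xc = &x[0] + static_cast<size_t>(c) * n;
    double* oc = &out[0] + static_cast<size_t>(c) * n_out;
    for (int j = 0; j < n_out; ++j) {
      const std::vector<double>& w = wj[j];
      const double* xk = xc + kj0[j];
      double acc = 0.0;
      for (size_t q = 0; q < w.size(); ++q) acc += w[q] * xk[q];
      oc[j] = acc;
    }
  }
  return out;
}

// Per-wavelength forward assembly of the simulator: for every channel ch
// and frame t, the shared perturbation S = task(t,ch)*coef_task(ch) +
// sys(t)*coef_sys(ch) drives intensity I = a0*exp(-S*L + sig_i*eps) and
// phase P = ph0 + S*dph + sig_p*eps'.  The measurement noise streams are
// generated internally (mt19937 + Gaussian) from `seed`, avoiding large R
// temporaries; a given seed reproduces the run exactly.
// [[Rcpp::export]]
List cpp_sim_mix(const NumericMatrix& task, const NumericVector& sys,
                 const NumericVector& coef_task, const NumericVector& coef_sys,
                 const NumericVector& pathlen, const NumericVector& dphase,
                 const NumericVector& a0, const NumericVector& ph0,
                 const NumericVector& sig_i, const NumericVector& sig_p,
                 int seed) {
  const int n = task.nrow(), m = task.ncol();
  NumericMatrix I(n, m), P(n, m);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  for (int c = 0; c < m; ++c) {
    const double ct = coef_task[c], cs = coef_sys[c], L = pathlen[c],
                 dp = dphase[c], A = a0[c], p0 = ph0[c], si = sig_i[c],
                 sp = sig_p[c];
    const double* tk = &task[0] + static_cast<size_t>(c) * n;
    const double* sy = &sys[0];
    double* Ic = &I[0] + static_cast<size_t>(c) * n;
    double* Pc = &P[0] + static_cast<size_t>(c) * n;
    for (int t = 0; t < n; ++t) {
      const double S = tk[t] * ct + sy[t] * cs;
      Ic[t] = A * std::exp(-S * L + si * gauss(rng));
      Pc[t] = p0 + S * dp + sp * gauss(rng);
    }
  }
  return List::create(_["intensity"] = I, _["phase"] = P);
}
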