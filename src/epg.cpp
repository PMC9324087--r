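#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Extended-phase-graph simulation of an inversion-prepared FISP fingerprint
// train for a batch of (T1, T2) pairs.
//
// State bookkeeping follows the usual configuration-state convention:
// F+(k), F-(k) = conj(F+(-k)), Z(k) for dephasing orders k = 0..T (one
// gradient-spoiler cycle per TR, so orders beyond T are never populated
// within a train).  RF pulses are applied with phase 0, under which the
// states keep a fixed structure -- F+ and F- stay purely imaginary and Z
// stays real when starting from thermal equilibrium -- so the recursion is
// carried in real arrays (F+ = i*f, F- = i*g, Z = z):
//   f' = cos^2(a/2) f + sin^2(a/2) g - sin(a) z
//   g' = sin^2(a/2) f + cos^2(a/2) g + sin(a) z
//   z' = (sin(a)/2) (f - g) + cos(a) z
// Within each TR the timing is: RF -> relax over TE -> echo (signal =
// F+(0)) -> relax over TR - TE -> gradient shift by one order (for the
// real arrays: f[0] <- -g[1], g[k] <- g[k+1]).  The train is cycled
// (inversion -> T frames -> recovery delay) n_rep times and the signal of
// the final cycle is returned, so incomplete recovery between repetitions
// is reflected in the fingerprint.
//
// Returns an n_entries x T complex matrix.
// [[Rcpp::export]]
ComplexMatrix epg_fisp_cpp(NumericVector flip_rad,
                           double tr_ms,
                           double te_ms,
                           NumericVector t1_ms,
                           NumericVector t2_ms,
                           double inv_eff,
                           double delay_ms,
                           int n_rep) {
  const int T = flip_rad.size();
  const int n = t1_ms.size();
  const int K = T + 1;  // dephasing orders 0..T
  ComplexMatrix out(n, T);

  // per-pulse mixing coefficients (shared by all entries)
  std::vector<double> ca(T), sa(T), c2(T), s2(T);
  for (int t = 0; t < T; ++t) {
    double a = flip_rad[t];
    ca[t] = std::cos(a);
    sa[t] = std::sin(a);
    double ch = std::cos(a / 2.0), sh = std::sin(a / 2.0);
    c2[t] = ch * ch;
    s2[t] = sh * sh;
  }

  std::vector<double> f(K), g(K), z(K);

  for (int e = 0; e < n; ++e) {
    const double T1 = t1_ms[e], T2 = t2_ms[e];
    const double e1_te = std::exp(-te_ms / T1);
    const double e2_te = std::exp(-te_ms / T2);
    const double e1_tr = std::exp(-(tr_ms - te_ms) / T1);
    const double e2_tr = std::exp(-(tr_ms - te_ms) / T2);
    const double e1_d = std::exp(-delay_ms / T1);
    const double e2_d = std::exp(-delay_ms / T2);

    std::fill(f.begin(), f.end(), 0.0);
    std::fill(g.begin(), g.end(), 0.0);
    std::fill(z.begin(), z.end(), 0.0);
    z[0] = 1.0;  // thermal equilibrium, M0 = 1

    int hi = 0;  // highest populated dephasing order (persists across cycles)
    for (int rep = 0; rep < n_rep; ++rep) {
      // adiabatic inversion: instantaneous Mz -> -eff * Mz
      for (int k = 0; k <= hi; ++k) z[k] *= -inv_eff;

      for (int t = 0; t < T; ++t) {
        const double cc = c2[t], ss = s2[t], s = sa[t], c = ca[t];
        for (int k = 0; k <= hi; ++k) {
          const double fk = f[k], gk = g[k], zk = z[k];
          f[k] = cc * fk + ss * gk - s * zk;
          g[k] = ss * fk + cc * gk + s * zk;
          z[k] = 0.5 * s * (fk - gk) + c * zk;
        }

        // relax to the echo time; the k = 0 transverse state forms the echo
        for (int k = 0; k <= hi; ++k) { f[k] *= e2_te; g[k] *= e2_te; z[k] *= e1_te; }
        z[0] += 1.0 - e1_te;
        out(e, t) = Rcomplex{0.0, f[0]};  // F+(0) = i * f[0]

        // relax over the remainder of the TR, then spoiler gradient shift
        for (int k = 0; k <= hi; ++k) { f[k] *= e2_tr; g[k] *= e2_tr; z[k] *= e1_tr; }
        z[0] += 1.0 - e1_tr;

        const int newhi = std::min(hi + 1, K - 1);
        for (int k = newhi; k >= 1; --k) f[k] = f[k - 1];
        f[0] = -g[1];
        for (int k = 0; k < newhi; ++k) g[k] = g[k + 1];
        g[newhi] = 0.0;
        hi = newhi;
      }

      // inter-repetition recovery delay
      for (int k = 0; k <= hi; ++k) { f[k] *= e2_d; g[k] *= e2_d; z[k] *= e1_d; }
      z[0] += 1.0 - e1_d;
    }
  }
  return out;
}
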