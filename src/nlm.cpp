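#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Non-local means denoising of a complex 2D image.
//
// Each pixel is replaced by a weight-normalized average over a centered
// search window of side `search`; weights are exp(-max(d - d0, 0) / h^2),
// where d is the mean squared modulus difference between the (odd-sided)
// patches around the two pixels and d0 compensates the distance expected
// between two patches of identical underlying signal under i.i.d. noise
// (so that equally noisy copies of the same structure receive weight ~1).
// The self-comparison, whose distance is exactly zero, would otherwise
// dominate the average; following standard practice it is assigned the
// maximum weight observed among the other candidates.  Real and imaginary
// parts share one weight set: the patch distance uses the complex modulus,
// so both parts are denoised jointly.  Near image borders patches are
// truncated to their valid overlap and the distance is normalized by the
// number of contributing pixels.
// [[Rcpp::export]]
ComplexMatrix nlm_cpp(ComplexMatrix img, int patch, int search, double h,
                      double d0) {
  const int nr = img.nrow(), nc = img.ncol();
  const int pr = patch / 2;                    // patch radius (patch is odd)
  const int s_lo = -(search / 2);              // search offsets, centered
  const int s_hi = (search - 1) / 2;
  const double h2 = h * h;
  ComplexMatrix out(nr, nc);

  std::vector<std::complex<double> > im(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      im[i + j * nr] = std::complex<double>(img(i, j).r, img(i, j).i);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double wsum = 0.0, wmax = 0.0;
      std::complex<double> acc(0.0, 0.0);
      for (int dj = s_lo; dj <= s_hi; ++dj) {
        int qj = j + dj;
        if (qj < 0 || qj >= nc) continue;
        for (int di = s_lo; di <= s_hi; ++di) {
          int qi = i + di;
          if (qi < 0 || qi >= nr) continue;
          if (di == 0 && dj == 0) continue;   // self handled afterwards
          // mean squared patch difference over the valid overlap
          double d = 0.0;
          int cnt = 0;
          for (int pj = -pr; pj <= pr; ++pj) {
            int aj = j + pj, bj = qj + pj;
            if (aj < 0 || aj >= nc || bj < 0 || bj >= nc) continue;
            for (int pi = -pr; pi <= pr; ++pi) {
              int ai = i + pi, bi = qi + pi;
              if (ai < 0 || ai >= nr || bi < 0 || bi >= nr) continue;
              std::complex<double> diff = im[ai + aj * nr] - im[bi + bj * nr];
              d += std::norm(diff);
              ++cnt;
            }
          }
          if (cnt == 0) continue;
          double dc = d / cnt - d0;
          if (dc < 0.0) dc = 0.0;
          double w = std::exp(-dc / h2);
          if (w > wmax) wmax = w;
          wsum += w;
          acc += w * im[qi + qj * nr];
        }
      }
      double wself = (wmax > 0.0) ? wmax : 1.0;
      wsum += wself;
      acc += wself * im[i + j * nr];
      out(i, j) = Rcomplex{acc.real() / wsum, acc.imag() / wsum};
    }
  }
  return out;
}
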