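#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sliding-window single-sided DFT amplitude, averaged over a set of
// in-band frequency bins.  x is a T-by-V matrix (time by voxel), the
// window has length w volumes and advances by s volumes, and kbins holds
// the DFT bin indices k (1 <= k < w/2) on the length-w grid, i.e.
// frequencies k/(w*TR).  Returns a V-by-nwin matrix whose (v, j) entry is
//   mean over k of (2/w) * |sum_{t=a_j}^{a_j+w-1} x[t, v] e^{-2 pi i k t / w}|
// with a_j = j*s.  The absolute-time demodulation differs from the
// window-local DFT only by a unit-modulus phase, so the amplitude is
// identical; the per-bin running sums make the whole stack O(T) per bin
// instead of O(T*w).  Per-window demeaning is a no-op for bins k >= 1.
// [[Rcpp::export(name = ".stft_band_amplitude")]]
NumericMatrix stft_band_amplitude(NumericMatrix x, int w, int s,
                                  IntegerVector kbins) {
  const int T = x.nrow(), V = x.ncol(), nb = kbins.size();
  if (w < 1 || w > T) stop("window length must be in [1, T]");
  if (s < 1) stop("window step must be >= 1");
  if (nb < 1) stop("no in-band frequency bins");
  const int nwin = (T - w) / s + 1;
  NumericMatrix out(V, nwin);

  std::vector< std::vector<double> > ct(nb), st(nb);
  for (int b = 0; b < nb; ++b) {
    ct[b].resize(T);
    st[b].resize(T);
    const double om = 2.0 * M_PI * (double)kbins[b] / (double)w;
    for (int t = 0; t < T; ++t) {
      ct[b][t] = std::cos(om * t);
      st[b][t] = std::sin(om * t);
    }
  }

  std::vector<double> pr(T + 1), pi(T + 1), acc(nwin);
  const double scale = 2.0 / ((double)w * (double)nb);
  for (int v = 0; v < V; ++v) {
    const double *xv = &x(0, v);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int b = 0; b < nb; ++b) {
      const double *c = ct[b].data(), *sn = st[b].data();
      pr[0] = 0.0; pi[0] = 0.0;
      for (int t = 0; t < T; ++t) {
        pr[t + 1] = pr[t] + xv[t] * c[t];
        pi[t + 1] = pi[t] - xv[t] * sn[t];
      }
      for (int j = 0; j < nwin; ++j) {
        const int a = j * s;
        const double dr = pr[a + w] - pr[a];
        const double di = pi[a + w] - pi[a];
        acc[j] += std::sqrt(dr * dr + di * di);
      }
    }
    for (int j = 0; j < nwin; ++j) out(v, j) = acc[j] * scale;
  }
  return out;
}

static void smooth_axis(std::vector<double> &buf, double *a,
                        int n_along, int stride, int n_lines,
                        int line_stride_outer, int n_outer,
                        const double *k, int r) {
  // Convolve along one axis with zero-padded boundary handling.
  for (int o = 0; o < n_outer; ++o) {
    for (int l = 0; l < n_lines; ++l) {
      double *line0 = a + (long)o * line_stride_outer + l;
      for (int i = 0; i < n_along; ++i) buf[i] = line0[(long)i * stride];
      for (int i = 0; i < n_along; ++i) {
        double acc = 0.0;
        const int lo = std::max(0, i - r), hi = std::min(n_along - 1, i + r);
        for (int j = lo; j <= hi; ++j) acc += buf[j] * k[j - i + r];
        line0[(long)i * stride] = acc;
      }
    }
  }
}

// Separable convolution of a 3D volume, or of every volume of a 4D
// array, with a 1D kernel applied along the three spatial axes.
// dims has length 3 or 4; kernel has odd length 2r+1.
// [[Rcpp::export(name = ".separable_smooth")]]
NumericVector separable_smooth(NumericVector arr, IntegerVector dims,
                               NumericVector kernel) {
  if (dims.size() < 3 || dims.size() > 4) stop("dims must have length 3 or 4");
  if (kernel.size() % 2 != 1) stop("kernel length must be odd");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nt = dims.size() == 4 ? dims[3] : 1;
  const long vol = (long)nx * ny * nz;
  if ((long)arr.size() != vol * nt) stop("array length does not match dims");
  const int r = (kernel.size() - 1) / 2;
  NumericVector out = clone(arr);
  double *a = REAL(out);
  const double *k = REAL(kernel);
  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  for (int t = 0; t < nt; ++t) {
    double *v = a + (long)t * vol;
    // x axis: stride 1, lines indexed over y*z by stride nx
    for (long yz = 0; yz < (long)ny * nz; ++yz) {
      double *line = v + yz * nx;
      for (int i = 0; i < nx; ++i) buf[i] = line[i];
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        const int lo = std::max(0, i - r), hi = std::min(nx - 1, i + r);
        for (int j = lo; j <= hi; ++j) acc += buf[j] * k[j - i + r];
        line[i] = acc;
      }
    }
    // y axis: for each z-slab, lines are the nx columns, stride nx
    smooth_axis(buf, v, ny, nx, nx, (long)nx * ny, nz, k, r);
    // z axis: stride nx*ny, lines are the nx*ny in-plane voxels
    smooth_axis(buf, v, nz, nx * ny, nx * ny, 0, 1, k, r);
  }
  return out;
}

// Inverse-DFT synthesis of band-limited series from in-band coefficients.
// re, im: nb-by-V standard-normal draws; kbins: the in-band bin indices on
// the length-n grid.  Column v of the result is
//   x[t] = (1/sqrt(nb)) * sum_b ( re[b,v] cos(2 pi k_b t / n)
//                               - im[b,v] sin(2 pi k_b t / n) ),
// i.e. the real inverse transform of Hermitian coefficients
// X_k = s (re + i im)/sqrt(2) with s = n / sqrt(2 nb), which gives unit
// expected variance per time point and exactly zero mean (no DC bin).
// [[Rcpp::export(name = ".band_synth")]]
NumericMatrix band_synth(NumericMatrix re, NumericMatrix im,
                         IntegerVector kbins, int n) {
  const int nb = re.nrow(), V = re.ncol();
  if (im.nrow() != nb || im.ncol() != V) stop("re/im shape mismatch");
  if (kbins.size() != nb) stop("kbins length must equal nrow(re)");
  NumericMatrix out(n, V);
  std::vector<double> ct((size_t)nb * n), st((size_t)nb * n);
  for (int b = 0; b < nb; ++b) {
    const double om = 2.0 * M_PI * (double)kbins[b] / (double)n;
    for (int t = 0; t < n; ++t) {
      ct[(size_t)b * n + t] = std::cos(om * t);
      st[(size_t)b * n + t] = std::sin(om * t);
    }
  }
  const double scale = 1.0 / std::sqrt((double)nb);
  for (int v = 0; v < V; ++v) {
    double *o = &out(0, v);
    for (int b = 0; b < nb; ++b) {
      const double a = re(b, v), c = im(b, v);
      const double *cb = &ct[(size_t)b * n], *sb = &st[(size_t)b * n];
      for (int t = 0; t < n; ++t) o[t] += a * cb[t] - c * sb[t];
    }
    for (int t = 0; t < n; ++t) o[t] *= scale;
  }
  return out;
}
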