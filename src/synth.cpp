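#include <Rcpp.h>
using namespace Rcpp;

// Evaluate the bolus-transit model for every pixel x frame and add
// shot-like Gaussian noise (sd = noise_level * sqrt(intensity)) in one
// pass. Pixels outside `idx_in` (0-based indices into the pixel vector)
// stay at their baseline. Uses R's RNG so results are reproducible under
// set.seed().
// [[Rcpp::export(name = ".synth_frames")]]
NumericMatrix synth_frames(NumericVector times, NumericVector b,
                           NumericVector t0, NumericVector A,
                           NumericVector Tr, NumericVector tau,
                           NumericVector rho, IntegerVector idx_in,
                           double noise_level) {
  const int npx = b.size();
  const int nt = times.size();
  NumericMatrix Y(npx, nt);

  for (int j = 0; j < nt; ++j) {
    const double t = times[j];
    double *col = &Y(0, j);
    for (int i = 0; i < npx; ++i) col[i] = b[i];
    for (int k = 0; k < idx_in.size(); ++k) {
      const int i = idx_in[k];
      const double u = t - t0[i];
      if (u <= 0) continue;
      double phase;
      if (u <= Tr[i]) {
        phase = (1.0 - std::cos(M_PI * u / Tr[i])) / 2.0;
      } else {
        phase = rho[i] + (1.0 - rho[i]) * std::exp(-(u - Tr[i]) / tau[i]);
      }
      col[i] = b[i] + A[i] * phase;
    }
  }
  if (noise_level > 0) {
    RNGScope scope;
    double *y = Y.begin();
    const R_xlen_t n = (R_xlen_t)npx * nt;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double s = y[i] > 0 ? noise_level * std::sqrt(y[i]) : 0.0;
      y[i] += norm_rand() * s;
      if (y[i] < 0) y[i] = 0;   // detector counts are nonnegative
    }
  }
  return Y;
}

// Gradient-magnitude image with 3x3 box smoothing (see
// gradient_magnitude() in R/motion.R for the rationale): central
// differences with replicated edges, then a separable box blur.
// [[Rcpp::export(name = ".grad_mag_blur")]]
NumericMatrix grad_mag_blur(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix g(nr, nc), v(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int jl = j > 0 ? j - 1 : 0, jr = j < nc - 1 ? j + 1 : nc - 1;
    for (int i = 0; i < nr; ++i) {
      const int iu = i > 0 ? i - 1 : 0, id = i < nr - 1 ? i + 1 : nr - 1;
      const double gx = m(i, jr) - m(i, jl);
      const double gy = m(id, j) - m(iu, j);
      g(i, j) = std::sqrt(gx * gx + gy * gy);
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const int iu = i > 0 ? i - 1 : 0, id = i < nr - 1 ? i + 1 : nr - 1;
      v(i, j) = g(iu, j) + g(i, j) + g(id, j);
    }
  for (int j = 0; j < nc; ++j) {
    const int jl = j > 0 ? j - 1 : 0, jr = j < nc - 1 ? j + 1 : nc - 1;
    for (int i = 0; i < nr; ++i)
      out(i, j) = (v(i, jl) + v(i, j) + v(i, jr)) / 9.0;
  }
  return out;
}
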