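#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Quadrature contraction for the bursty-model log generating function.
// For grid points (i, j) and quadrature nodes q:
//   f = gu[i] * eb[q] + gs[j] * wcoef[q]
//   acc[i, j] = sum_q w[q] * b * f / (1 - b * f)
// gu, gs are complex grid factors; eb, wcoef, w are real node vectors.
// [[Rcpp::export]]
ComplexMatrix gf_quad_cpp(ComplexVector gu, ComplexVector gs,
                          NumericVector eb, NumericVector wcoef,
                          NumericVector w, double b) {
  const int Nu = gu.size(), Ns = gs.size(), Q = eb.size();
  std::vector< std::complex<double> > cu(Nu), cs(Ns);
  for (int i = 0; i < Nu; ++i) cu[i] = std::complex<double>(gu[i].r, gu[i].i);
  for (int j = 0; j < Ns; ++j) cs[j] = std::complex<double>(gs[j].r, gs[j].i);
  ComplexMatrix acc(Nu, Ns);
  for (int j = 0; j < Ns; ++j) {
    const double sr = cs[j].real(), si = cs[j].imag();
    for (int i = 0; i < Nu; ++i) {
      const double ur = cu[i].real(), ui = cu[i].imag();
      double ar = 0.0, ai = 0.0;
      for (int q = 0; q < Q; ++q) {
        // bf = x + iy;  bf / (1 - bf) = (x - (x^2 + y^2) + i y) / |1 - bf|^2
        const double x = b * (ur * eb[q] + sr * wcoef[q]);
        const double y = b * (ui * eb[q] + si * wcoef[q]);
        const double n2 = x * x + y * y;
        const double den = 1.0 - 2.0 * x + n2;
        const double wq = w[q] / den;
        ar += wq * (x - n2);
        ai += wq * y;
      }
      acc(i, j).r = ar;
      acc(i, j).i = ai;
    }
  }
  return acc;
}

// Stationary sampler for the bursty two-stage model via Gillespie simulation.
// Reactions (k = 1): burst -> U += Geom(mean b); U -> S at rate beta per
// molecule; S -> 0 at rate gamma per molecule. One independent trajectory per
// cell, started empty and burned in for `burnin` time units. Uses R's RNG so
// set.seed() governs reproducibility.
// [[Rcpp::export]]
IntegerMatrix gillespie_counts_cpp(int n_cells, double b, double beta,
                                   double gamma, double burnin) {
  IntegerMatrix out(n_cells, 2);
  const double p_geom = 1.0 / (1.0 + b); // geometric on {0,1,...}, mean b
  for (int c = 0; c < n_cells; ++c) {
    double t = 0.0;
    long u = 0, s = 0;
    while (true) {
      double r_burst = 1.0, r_spl = beta * u, r_dec = gamma * s;
      double rtot = r_burst + r_spl + r_dec;
      t += R::rexp(1.0 / rtot);
      if (t > burnin) break;
      double pick = R::runif(0.0, rtot);
      if (pick < r_burst) {
        u += (long) R::rgeom(p_geom);
      } else if (pick < r_burst + r_spl) {
        --u; ++s;
      } else {
        --s;
      }
    }
    out(c, 0) = (int) u;
    out(c, 1) = (int) s;
  }
  return out;
}
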