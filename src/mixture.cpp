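// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>

// Gaussian row log-densities for the two mixture components.
// Y: genes x 2n traits (species-major interleaved).
// blocks: 2 x 2 x k cube of e^{-H d} Vinf e^{-H' d} for the unique divergence
//         times; didx: n x n 0-based indices into the cube.
// A: 2n x 2 optima design matrix; m: prior means; vprior: prior variances;
// vwn: white-noise variances per trait.
// Returns genes x 2 matrix: column 0 phylo log-density, column 1 white-noise.
// [[Rcpp::export]]
arma::mat mixture_components_cpp(const arma::mat& Y, const arma::cube& blocks,
                                 const arma::imat& didx, const arma::mat& A,
                                 const arma::vec& m, const arma::vec& vprior,
                                 const arma::vec& vwn) {
  const int n = didx.n_rows, n2 = 2 * n, G = Y.n_rows;
  arma::mat Vp(n2, n2);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      Vp.submat(2 * i, 2 * j, 2 * i + 1, 2 * j + 1) = blocks.slice(didx(i, j));
    }
  }
  Vp = 0.5 * (Vp + Vp.t());
  arma::mat prior_term = A * arma::diagmat(vprior) * A.t();
  Vp += prior_term;
  arma::mat Vw = prior_term;
  for (int i = 0; i < n; ++i) {
    Vw(2 * i, 2 * i) += vwn(0);
    Vw(2 * i + 1, 2 * i + 1) += vwn(1);
  }
  arma::vec mu = A * m;
  arma::mat Yc = Y.t();
  Yc.each_col() -= mu;

  const double l2pi = std::log(2.0 * M_PI);
  arma::mat out(G, 2);
  for (int c = 0; c < 2; ++c) {
    arma::mat V = (c == 0) ? Vp : Vw;
    V = 0.5 * (V + V.t());
    if (!V.is_finite()) Rcpp::stop("covariance has non-finite entries");
    arma::mat R;
    double jit = 0.0;
    bool ok = arma::chol(R, V);
    while (!ok) {
      jit = (jit == 0.0) ? 1e-12 : jit * 10.0;
      if (jit > 1e-9) Rcpp::stop("covariance not PSD within jitter tolerance");
      ok = arma::chol(R, V + jit * arma::eye(n2, n2));
    }
    if (R.diag().min() < 1e-150) Rcpp::stop("degenerate covariance factor");
    double logdet = 2.0 * arma::accu(arma::log(R.diag()));
    arma::mat W = arma::solve(arma::trimatl(R.t()), Yc);
    arma::rowvec q = arma::sum(W % W, 0);
    for (int g = 0; g < G; ++g) out(g, c) = -0.5 * (n2 * l2pi + logdet + q(g));
  }
  return out;
}
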