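#' Kinetic parameters of the bursty transcription model
#'
#' The model: transcriptional bursts arrive as a Poisson process at rate
#' `k == 1` (all rates are expressed in units of the burst initiation rate,
#' which is not identifiable from a stationary snapshot); each burst adds a
#' geometric number of unspliced molecules with mean `b` (support `0, 1, ...`);
#' unspliced molecules convert to spliced at per-molecule rate `beta`; spliced
#' molecules decay at per-molecule rate `gamma`. Optional Poisson technical
#' noise: each molecule class is observed as a Poisson count with intensity
#' `lambda * (true count)`; `lambda = NULL` (or `Inf`) disables noise for that
#' class.
#'
#' @param b Mean burst size, > 0.
#' @param beta Splicing rate in units of k, > 0.
#' @param gamma Decay rate in units of k, > 0.
#' @param lambda_u,lambda_s Poisson capture intensities per molecule
#'   (`NULL` = noise-free).
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(b, beta, gamma, lambda_u = NULL, lambda_s = NULL) {
  vals <- c(b = b, beta = beta, gamma = gamma)
  if (any(!is.finite(vals)) || any(vals <= 0)) stop("b, beta, gamma must be finite and > 0")
  norm_lambda <- function(l) {
    if (is.null(l) || !is.finite(l)) return(NULL)
    if (l < 0) stop("lambda must be >= 0")
    l
  }
  structure(list(b = b, beta = beta, gamma = gamma,
                 lambda_u = norm_lambda(lambda_u), lambda_s = norm_lambda(lambda_s)),
            class = "kinetic_params")
}

# First two moments of the (possibly noise-observed) marginals; k = 1.
# U is negative binomial (shape 1/beta, mean b/beta, Fano 1 + b);
# S has mean b/gamma and Fano 1 + b * beta / (beta + gamma).
# Poisson(lambda * X) observation maps (m, v) -> (lambda m, lambda^2 v + lambda m).
marginal_moments <- function(params) {
  mu_u <- params$b / params$beta
  va_u <- mu_u * (1 + params$b)
  mu_s <- params$b / params$gamma
  va_s <- mu_s * (1 + params$b * params$beta / (params$beta + params$gamma))
  obs <- function(m, v, l) if (is.null(l)) c(m, v) else c(l * m, l * l * v + l * m)
  u <- obs(mu_u, va_u, params$lambda_u)
  s <- obs(mu_s, va_s, params$lambda_s)
  list(mean_u = u[1], var_u = u[2], mean_s = s[1], var_s = s[2])
}

# Grid size: mean + 15 sd of the marginal, floor 16, rounded to a power of 2
default_grid <- function(params, max_u = NULL, max_s = NULL) {
  mo <- marginal_moments(params)
  nu <- ceiling(mo$mean_u + 15 * sqrt(mo$var_u)) + 1
  ns <- ceiling(mo$mean_s + 15 * sqrt(mo$var_s)) + 1
  nu <- max(16, nu, if (is.null(max_u)) 0 else max_u + 1)
  ns <- max(16, ns, if (is.null(max_s)) 0 else max_s + 1)
  c(2^ceiling(log2(nu)), 2^ceiling(log2(ns)))
}

# log generating function of the stationary law evaluated on a 2-D
# roots-of-unity grid, by quadrature of
#   log G(x_u, x_s) = k * int_0^inf  b f(s) / (1 - b f(s)) ds,
#   f(s) = g_u e^{-beta s} + g_s * beta (e^{-gamma s} - e^{-beta s}) / (beta - gamma),
# with g = x - 1 (noise-free) or g = exp(lambda (x - 1)) - 1 (Poisson noise).
# Double-exponential (exp-sinh) quadrature s = exp(pi/2 sinh z) / min(beta,
# gamma): the integrand's algebraic behavior in e^{-s} at both ends is
# flattened double-exponentially, so the trapezoid rule in z converges
# geometrically; the z range covers s from ~6e-16 to where e^{-min*s}
# underflows.
log_gf_grid <- function(params, Nu, Ns, n_quad) {
  b <- params$b; beta <- params$beta; gamma <- params$gamma
  xu <- exp(2i * pi * (0:(Nu - 1)) / Nu)
  xs <- exp(2i * pi * (0:(Ns - 1)) / Ns)
  gu <- if (is.null(params$lambda_u)) xu - 1 else exp(params$lambda_u * (xu - 1)) - 1
  gs <- if (is.null(params$lambda_s)) xs - 1 else exp(params$lambda_s * (xs - 1)) - 1
  r <- min(beta, gamma)
  z <- seq(-3.9, 2.6, length.out = n_quad)
  h <- z[2] - z[1]
  s <- exp(pi / 2 * sinh(z)) / r
  w <- h * s * (pi / 2) * cosh(z)
  eb <- exp(-beta * s)
  wcoef <- if (abs(beta - gamma) < 1e-9 * max(beta, gamma)) {
    beta * s * eb
  } else {
    beta * (exp(-gamma * s) - eb) / (beta - gamma)
  }
  gf_quad_cpp(gu, gs, eb, wcoef, w, b)
}

#' Stationary joint PMF of spliced and unspliced counts
#'
#' Numerically solves the chemical master equation of the bursty model at
#' steady state via its probability generating function, evaluated on a 2-D
#' roots-of-unity grid and inverted by FFT. Poisson technical noise enters by
#' composing the generating function with the Poisson observation kernel.
#' Quadrature is adaptive: the number of Gauss-Legendre nodes is doubled until
#' the log-generating-function values change by less than `quad_tol`; the grid
#' is doubled when the retained probability mass falls below `1 - mass_tol`.
#'
#' @param params A [kinetic_params()].
#' @param max_u,max_s Optional minimum truncation bounds (the grid is enlarged
#'   automatically to cover the distribution's bulk and any observed counts).
#' @param quad_tol Absolute quadrature tolerance on the log generating
#'   function (default 1e-10).
#' @param mass_tol Maximum tolerated mass deficit on the truncated grid.
#' @param n_quad Fixed number of quadrature nodes; `NULL` (default) selects
#'   the count adaptively by doubling until the log generating function is
#'   stable to `quad_tol`.
#' @return Matrix `P` with `P[u + 1, s + 1] = P(U = u, S = s)`; attributes
#'   `mass` (retained mass) and `grid` (dimensions).
#' @export
steady_state_pmf <- function(params, max_u = NULL, max_s = NULL,
                             quad_tol = 1e-10, mass_tol = 1e-6, n_quad = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  gr <- default_grid(params, max_u, max_s)
  for (attempt in 1:6) {
    Nu <- gr[1]; Ns <- gr[2]
    if (!is.null(n_quad)) {
      lg <- log_gf_grid(params, Nu, Ns, n_quad)
    } else {
      nq <- 96
      lg <- log_gf_grid(params, Nu, Ns, nq)
      repeat {
        nq <- 2L * nq
        lg2 <- log_gf_grid(params, Nu, Ns, nq)
        if (max(abs(lg2 - lg)) < quad_tol || nq >= 3072) { lg <- lg2; break }
        lg <- lg2
      }
    }
    P <- Re(stats::fft(exp(lg))) / (Nu * Ns)
    P[P < 0] <- 0
    mass <- sum(P)
    if (mass >= 1 - mass_tol) {
      attr(P, "mass") <- mass
      attr(P, "grid") <- c(Nu, Ns)
      return(P)
    }
    gr <- gr * 2L   # mass deficit: enlarge truncation
  }
  stop(sprintf("PMF truncation failed: retained mass %.8f after grid growth", mass))
}

#' Log-likelihood of paired counts for one gene
#'
#' Sums `log P(U = u_c, S = s_c)` over cells, with the stationary PMF from
#' [steady_state_pmf()]. The PMF grid always covers the observed counts, so
#' out-of-grid data trigger enlargement rather than silent `-Inf`. Identical
#' (u, s) pairs are collapsed before evaluation, so cost is independent of the
#' number of cells.
#'
#' @param u,s Nonnegative integer vectors of equal length (one entry per cell).
#' @param params A [kinetic_params()].
#' @param quad_tol,n_quad Passed to [steady_state_pmf()].
#' @return Scalar log-likelihood.
#' @export
counts_loglik <- function(u, s, params, quad_tol = 1e-10, n_quad = NULL) {
  if (length(u) == 0L || length(u) != length(s)) stop("u and s must be nonempty, equal length")
  if (any(u < 0) || any(s < 0)) stop("negative counts")
  P <- steady_state_pmf(params, max_u = max(u), max_s = max(s),
                        quad_tol = quad_tol, n_quad = n_quad)
  tab <- table(u, s)
  uu <- as.integer(rownames(tab)); ss <- as.integer(colnames(tab))
  logP <- log(pmax(P[uu + 1, ss + 1, drop = FALSE], 1e-300))
  sum(tab * logP)
}

# Closed-form negative-binomial U marginal (noise-free):
# shape k/beta = 1/beta, success probability b/(1+b)
nb_u_marginal <- function(b, beta, max_u) {
  stats::dnbinom(0:max_u, size = 1 / beta, prob = 1 / (1 + b))
}
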