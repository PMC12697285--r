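#' Gaussian prior on gene-level optima
#'
#' Gene-specific optima `theta = (theta_c, theta_mu)` — the optimum of the
#' constrained coordinate and the optimal log mean spliced expression — are
#' modeled as draws from independent normals and integrated out analytically,
#' which adds the rank-2 term `A diag(v_c, v_mu) A'` to the tip covariance.
#'
#' @param m_c,m_mu Prior means.
#' @param v_c,v_mu Prior variances, >= 0.
#' @return List of class `optima_prior`.
#' @export
optima_prior <- function(m_c = 0, m_mu = 0, v_c = 0.3, v_mu = 0.3) {
  if (v_c < 0 || v_mu < 0) stop("prior variances must be nonnegative")
  structure(list(m_c = m_c, m_mu = m_mu, v_c = v_c, v_mu = v_mu),
            class = "optima_prior")
}

#' White-noise component variances
#'
#' Variances of the species-independent (no phylogenetic signal) component,
#' per trait; species are exchangeable under this component.
#'
#' @param v_wn_b,v_wn_gamma Per-trait variances, > 0.
#' @return List of class `wn_spec`.
#' @export
white_noise_spec <- function(v_wn_b = 0.3, v_wn_gamma = 0.3) {
  if (v_wn_b <= 0 || v_wn_gamma <= 0) stop("white-noise variances must be > 0")
  structure(list(v_wn_b = v_wn_b, v_wn_gamma = v_wn_gamma), class = "wn_spec")
}

# Mean vector and covariance of the optima-marginalized phylogenetic
# component: N(A m, V_tips + A diag(v) A')
phylo_marginal <- function(div, spec, prior) {
  A <- optima_design_matrix(spec$kind, div$n_tips)
  V <- tip_covariance(div, spec, check_psd = FALSE) +
       A %*% diag(c(prior$v_c, prior$v_mu)) %*% t(A)
  list(mean = as.numeric(A %*% c(prior$m_c, prior$m_mu)), cov = V)
}

# White-noise marginal: species-iid residuals around the same optima structure
wn_marginal <- function(kind, n_tips, prior, wn) {
  A <- optima_design_matrix(kind, n_tips)
  D <- diag(rep(c(wn$v_wn_b, wn$v_wn_gamma), n_tips))
  V <- D + A %*% diag(c(prior$v_c, prior$v_mu)) %*% t(A)
  list(mean = as.numeric(A %*% c(prior$m_c, prior$m_mu)), cov = V)
}

# Cholesky with escalating diagonal jitter; records jitter used
chol_jitter <- function(V, max_jitter = 1e-9) {
  jit <- 0
  repeat {
    R <- tryCatch(chol(V + diag(jit, nrow(V))), error = function(e) NULL)
    if (!is.null(R)) return(structure(R, jitter = jit))
    jit <- if (jit == 0) 1e-12 else jit * 10
    if (jit > max_jitter) stop("covariance not PSD within jitter tolerance")
  }
}

# log N(y_g; mean, V) for every row of Y, via one Cholesky factorization
mvn_loglik_rows <- function(Y, mean, V) {
  R <- chol_jitter(V)
  Yc <- sweep(Y, 2, mean)
  W <- backsolve(R, t(Yc), transpose = TRUE)
  q <- colSums(W * W)
  -0.5 * (ncol(Y) * log(2 * pi) + 2 * sum(log(diag(R))) + q)
}

#' Marginalized phylogenetic log-density of one gene's trait vector
#'
#' Log-density of the length-`2n` trait vector under the coevolution OU model
#' with the gene's optima integrated out over the Gaussian prior:
#' `log N(y; A m, V_tips + A diag(v_c, v_mu) A')`.
#'
#' @param y Length-`2n` numeric vector, species-major `(b, gamma)` pairs.
#' @param div A [divergence_structure()].
#' @param spec A [coevo_model_spec()].
#' @param prior An [optima_prior()].
#' @return Scalar log-density.
#' @export
gene_loglik_phylo <- function(y, div, spec, prior) {
  m <- phylo_marginal(div, spec, prior)
  if (length(y) != length(m$mean)) stop("trait vector length must be 2 * n_tips")
  as.numeric(mvn_loglik_rows(matrix(y, 1), m$mean, m$cov))
}

#' White-noise log-density of one gene's trait vector
#'
#' Species-exchangeable component: iid per-species residuals
#' `diag(v_wn_b, v_wn_gamma)` around the optima-prior mean structure, no tree
#' dependence.
#'
#' @param y Length-`2n` trait vector.
#' @param prior An [optima_prior()].
#' @param wn A [white_noise_spec()].
#' @param kind Model kind (sets the optima design matrix).
#' @return Scalar log-density.
#' @export
gene_loglik_whitenoise <- function(y, prior, wn, kind) {
  n <- length(y) / 2
  if (n != round(n)) stop("trait vector length must be even")
  m <- wn_marginal(kind, n, prior, wn)
  as.numeric(mvn_loglik_rows(matrix(y, 1), m$mean, m$cov))
}

#' Mixture log-likelihood of a trait table
#'
#' Per gene, `logsumexp(log(1 - p_wn) + L_phylo, log(p_wn) + L_wn)`, summed
#' over genes; exact at the boundaries `p_wn = 0` and `p_wn = 1`.
#'
#' @param traits A [trait_table()].
#' @param div A [divergence_structure()].
#' @param spec A [coevo_model_spec()].
#' @param prior An [optima_prior()].
#' @param wn A [white_noise_spec()].
#' @param p_wn Mixture weight of the white-noise component, in `[0, 1]`.
#' @return Scalar total log-likelihood.
#' @export
mixture_loglik <- function(traits, div, spec, prior, wn, p_wn) {
  if (p_wn < 0 || p_wn > 1) stop("p_wn must lie in [0, 1]")
  comp <- component_logliks(traits$Y, div, spec, prior, wn)
  sum(mix_rowwise(comp$lp, comp$lw, p_wn))
}

# fast path used by the fitting loop: unique-divergence OU blocks assembled
# and factorized in compiled code
component_logliks <- function(Y, div, spec, prior, wn) {
  if (is.null(div$dvals)) {
    div$dvals <- unique(as.vector(div$d))
    div$didx <- matrix(match(div$d, div$dvals) - 1L, div$n_tips, div$n_tips)
  }
  H <- selection_matrix(spec)
  Vinf <- stationary_covariance(spec)
  k <- length(div$dvals)
  blocks <- array(0, c(2, 2, k))
  for (i in seq_len(k)) {
    E <- expm2(-H * div$dvals[i])
    blocks[, , i] <- E %*% Vinf %*% t(E)
  }
  A <- optima_design_matrix(spec$kind, div$n_tips)
  out <- mixture_components_cpp(Y, blocks, div$didx, A,
                                c(prior$m_c, prior$m_mu),
                                c(prior$v_c, prior$v_mu),
                                c(wn$v_wn_b, wn$v_wn_gamma))
  list(lp = out[, 1], lw = out[, 2])
}

mix_rowwise <- function(lp, lw, p_wn) {
  if (p_wn == 0) return(lp)
  if (p_wn == 1) return(lw)
  a <- log1p(-p_wn) + lp
  b <- log(p_wn) + lw
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Fit the phylogenetic mixture model by maximum likelihood
#'
#' Maximizes [mixture_loglik()] over the shared evolutionary parameters
#' `(alpha_b, alpha_gamma, sigma_b, sigma_gamma)`, the mixture weight `p_wn`,
#' the optima-prior hyperparameters `(m_c, m_mu, v_c, v_mu)` and the
#' white-noise variances, with log transforms on positive parameters and a
#' logit on `p_wn` (clipped to `[1e-6, 1 - 1e-6]` during optimization).
#' Multi-start bounded quasi-Newton: one moment-based start plus random
#' log-uniform starts, all driven by `seed`.
#'
#' @param traits A [trait_table()].
#' @param tree A `phylo` tree or a [divergence_structure()].
#' @param kind Model kind to fit.
#' @param n_starts Number of optimizer starts.
#' @param fix_prior_means If `TRUE`, pins `m_c = m_mu = 0` (natural for
#'   per-species mean-centered traits) and drops 2 parameters.
#' @param seed Integer seed for the random starts.
#' @param maxit Iteration cap per start.
#' @return An object of class `mixture_fit` with the fitted `spec`, `prior`,
#'   `wn`, `p_wn`, `loglik`, `n_params`, `aic`, per-gene white-noise posterior
#'   probabilities, convergence info and the data fingerprint.
#' @export
fit_mixture <- function(traits, tree, kind = c("gamma_constrained",
                                               "b_constrained", "independent"),
                        n_starts = 10, fix_prior_means = FALSE, seed = 1,
                        maxit = 400) {
  kind <- match.arg(kind)
  div <- if (inherits(tree, "divergence")) tree else divergence_structure(tree)
  Y <- traits$Y
  if (nrow(Y) < 2) stop("need at least 2 genes")
  if (div$n_tips < 2) stop("need at least 2 species")
  if (div$n_tips != length(traits$species)) stop("tree/trait species mismatch")

  T0 <- div$tip_depth
  unpack <- function(th) {
    i <- 0L
    nx <- function() { i <<- i + 1L; th[i] }
    spec <- coevo_model_spec(kind, exp(nx()), exp(nx()), exp(nx()), exp(nx()))
    p_wn <- stats::plogis(nx())
    if (fix_prior_means) { m_c <- 0; m_mu <- 0 } else { m_c <- nx(); m_mu <- nx() }
    prior <- optima_prior(m_c, m_mu, exp(nx()), exp(nx()))
    wn <- white_noise_spec(exp(nx()), exp(nx()))
    list(spec = spec, p_wn = p_wn, prior = prior, wn = wn)
  }
  negll <- function(th) {
    pars <- tryCatch(unpack(th), error = function(e) NULL)
    if (is.null(pars)) return(1e12)
    ll <- tryCatch({
      comp <- component_logliks(Y, div, pars$spec, pars$prior, pars$wn)
      sum(mix_rowwise(comp$lp, comp$lw, pars$p_wn))
    }, error = function(e) NA_real_)
    if (!is.finite(ll)) 1e12 else -ll
  }

  # moment-based start: cross-species trait variances set the scales
  vb <- mean(apply(Y[, seq(1, ncol(Y), 2), drop = FALSE], 2, var))
  vg <- mean(apply(Y[, seq(2, ncol(Y), 2), drop = FALSE], 2, var))
  mb <- mean(Y[, seq(1, ncol(Y), 2)]); mg <- mean(Y[, seq(2, ncol(Y), 2)])
  mm <- switch(kind,
    gamma_constrained = c(mg, mb - mg),
    b_constrained     = c(mb, mb - mg),
    independent       = c(mb, mg))
  a0 <- 2 / T0
  th_mom <- c(log(a0), log(a0),
              log(sqrt(pmax(2 * a0 * vb * 0.5, 1e-6))),
              log(sqrt(pmax(2 * a0 * vg * 0.5, 1e-6))),
              stats::qlogis(0.2),
              if (fix_prior_means) NULL else mm,
              log(pmax(0.3 * c(vb, vg), 1e-6)),
              log(pmax(0.5 * c(vb, vg), 1e-6)))
  np <- length(th_mom)
  lo_rate <- log(1e-4 / T0); hi_rate <- log(1e4 / T0)
  lower <- c(rep(lo_rate, 2), rep(log(1e-4), 2), stats::qlogis(1e-6),
             if (fix_prior_means) NULL else c(-20, -20), rep(log(1e-8), 4))
  upper <- c(rep(hi_rate, 2), rep(log(1e3), 2), stats::qlogis(1 - 1e-6),
             if (fix_prior_means) NULL else c(20, 20), rep(log(1e4), 4))
  th_mom <- pmin(pmax(th_mom, lower), upper)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  starts <- list(th_mom)
  if (n_starts > 1) {
    for (r in 2:n_starts) {
      th <- c(log(exp(runif(2, log(0.2), log(60))) / T0),
              log(exp(runif(2, log(0.05), log(5)))),
              stats::qlogis(runif(1, 0.05, 0.6)),
              if (fix_prior_means) NULL else mm + rnorm(2, 0, 0.5),
              log(pmax(c(vb, vg) * exp(runif(2, log(0.05), log(2))), 1e-6)),
              log(pmax(c(vb, vg) * exp(runif(2, log(0.05), log(2))), 1e-6)))
      starts[[r]] <- pmin(pmax(th, lower), upper)
    }
  }
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      optim(th0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e12) stop("all optimizer starts failed")

  pars <- unpack(best$par)
  loglik <- -best$value
  # boundary-converged p_wn is reported unclipped
  p_hat <- pars$p_wn
  boundary <- FALSE
  if (p_hat <= 1.5e-6) { p_hat <- 0; boundary <- TRUE }
  if (p_hat >= 1 - 1.5e-6) { p_hat <- 1; boundary <- TRUE }
  comp <- component_logliks(Y, div, pars$spec, pars$prior, pars$wn)
  post <- posterior_from_components(comp$lp, comp$lw, p_hat)
  structure(list(
    kind = kind, spec = pars$spec, prior = pars$prior, wn = pars$wn,
    p_wn = p_hat, p_wn_boundary = boundary,
    loglik = loglik, n_params = np, aic = 2 * np - 2 * loglik,
    posterior_wn = setNames(post, traits$gene_ids),
    converged = best$convergence == 0, seed = seed, n_starts = n_starts,
    fingerprint = data_fingerprint(traits)),
    class = "mixture_fit")
}

data_fingerprint <- function(traits) {
  c(n_genes = nrow(traits$Y), n_species = length(traits$species),
    sum = sum(traits$Y), sumsq = sum(traits$Y^2))
}

posterior_from_components <- function(lp, lw, p_wn) {
  if (p_wn == 0) return(rep(0, length(lp)))
  if (p_wn == 1) return(rep(1, length(lp)))
  a <- log1p(-p_wn) + lp
  b <- log(p_wn) + lw
  1 / (1 + exp(a - b))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture fit [%s]: logL = %.2f, AIC = %.2f (k = %d)\n",
              x$kind, x$loglik, x$aic, x$n_params))
  cat(sprintf("  alpha_b = %.4g, alpha_gamma = %.4g, sigma_b = %.4g, sigma_gamma = %.4g\n",
              x$spec$alpha_b, x$spec$alpha_gamma, x$spec$sigma_b, x$spec$sigma_gamma))
  cat(sprintf("  p_wn = %.3f%s\n", x$p_wn, if (x$p_wn_boundary) " (boundary)" else ""))
  invisible(x)
}

#' Rank mixture fits by AIC
#'
#' @param fits List of `mixture_fit` objects fitted to the same trait table.
#' @return data.frame with `model`, `n_params`, `loglik`, `aic`, `delta_aic`,
#'   sorted ascending by AIC.
#' @export
compare_models <- function(fits) {
  if (!length(fits)) stop("no fits")
  fps <- lapply(fits, `[[`, "fingerprint")
  if (length(fits) > 1 &&
      !all(vapply(fps[-1], function(f) isTRUE(all.equal(f, fps[[1]])), TRUE))) {
    stop("fits were not computed on identical data")
  }
  tb <- data.frame(
    model = vapply(fits, `[[`, "", "kind"),
    n_params = vapply(fits, function(f) as.integer(f$n_params), 0L),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"),
    stringsAsFactors = FALSE)
  tb <- tb[order(tb$aic), , drop = FALSE]
  tb$delta_aic <- tb$aic - tb$aic[1]
  rownames(tb) <- NULL
  tb
}

#' Per-gene posterior white-noise probabilities
#'
#' Mixture responsibilities `p(wn | gene)` under a fitted model, recomputed on
#' (possibly new) traits.
#'
#' @param fit A `mixture_fit`.
#' @param traits A [trait_table()].
#' @param tree Tree or divergence structure.
#' @return Named numeric vector in `[0, 1]`.
#' @export
posterior_wn_probs <- function(fit, traits, tree) {
  div <- if (inherits(tree, "divergence")) tree else divergence_structure(tree)
  comp <- component_logliks(traits$Y, div, fit$spec, fit$prior, fit$wn)
  setNames(posterior_from_components(comp$lp, comp$lw, fit$p_wn), traits$gene_ids)
}

#' Split genes into covariate bins and refit per bin
#'
#' Genes are ranked by the scalar covariate (ties broken by stable gene-id
#' order) and split into `n_bins` groups. Remainder genes are assigned to the
#' outer bins first, so 167 genes in 3 bins give sizes (56, 55, 56).
#'
#' @param traits A [trait_table()].
#' @param tree Tree or divergence structure.
#' @param kind Model kind.
#' @param covariate Named (or traits-ordered) numeric vector, one per gene.
#' @param n_bins Number of bins (default 3, expression terciles).
#' @param ... Passed to [fit_mixture()].
#' @return List with `fits` (per bin), `sizes`, and `bins` (per-gene bin index
#'   in covariate-ascending order).
#' @export
fit_by_bins <- function(traits, tree, kind, covariate, n_bins = 3, ...) {
  G <- nrow(traits$Y)
  if (!is.null(names(covariate))) covariate <- covariate[traits$gene_ids]
  if (length(covariate) != G || anyNA(covariate)) stop("covariate must cover all genes")
  sizes <- bin_sizes(G, n_bins)
  if (any(sizes < 2)) stop("a bin would contain fewer than 2 genes")
  ord <- order(covariate, seq_len(G))   # stable tie-break by gene order
  bins <- integer(G)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  fits <- lapply(seq_len(n_bins), function(k) {
    idx <- which(bins == k)
    sub <- structure(list(gene_ids = traits$gene_ids[idx],
                          species = traits$species,
                          Y = traits$Y[idx, , drop = FALSE]),
                     class = "trait_table")
    fit_mixture(sub, tree, kind, ...)
  })
  list(fits = fits, sizes = sizes, bins = bins)
}

# remainder goes to the outer bins, outermost first (56, 55, 56 for N = 167)
bin_sizes <- function(N, n_bins) {
  base <- N %/% n_bins
  rem <- N - base * n_bins
  sizes <- rep(base, n_bins)
  if (rem > 0) {
    idx <- order(abs(seq_len(n_bins) - (n_bins + 1) / 2), decreasing = TRUE)
    sizes[idx[seq_len(rem)]] <- base + 1
  }
  sizes
}
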