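test_that("marginalized phylogenetic likelihood matches Monte-Carlo integration", {
  set.seed(42)
  div <- divergence_structure(tree4())
  prior <- optima_prior(m_c = 0.2, m_mu = -0.1, v_c = 0.4, v_mu = 0.25)
  for (sp in list(spec_gamma(), spec_b(), spec_indep())) {
    y <- rnorm(8, 0, 0.6)
    ll <- gene_loglik_phylo(y, div, sp, prior)
    A <- optima_design_matrix(sp$kind, div$n_tips)
    V <- tip_covariance(div, sp)
    mc <- mc_marginal_loglik(y, V, A, prior, n_draws = 4e5)
    expect_lt(abs(ll - mc), 0.02)
  }
})

test_that("white-noise likelihood matches Monte-Carlo integration and is exchangeable", {
  set.seed(43)
  prior <- optima_prior(m_c = 0.1, m_mu = 0.3, v_c = 0.3, v_mu = 0.2)
  wn <- white_noise_spec(0.5, 0.4)
  y <- rnorm(8, 0, 0.7)
  ll <- gene_loglik_whitenoise(y, prior, wn, "gamma_constrained")
  D <- diag(rep(c(0.5, 0.4), 4))
  A <- optima_design_matrix("gamma_constrained", 4)
  mc <- mc_marginal_loglik(y, D, A, prior, n_draws = 4e5)
  expect_lt(abs(ll - mc), 0.02)
  # permuting species leaves the white-noise density unchanged
  perm <- c(3, 1, 4, 2)
  yp <- as.numeric(matrix(y, 2)[, perm])
  expect_equal(gene_loglik_whitenoise(yp, prior, wn, "gamma_constrained"), ll,
               tolerance = 1e-10)
})

test_that("degenerate prior reduces to the fixed-optimum likelihood", {
  div <- divergence_structure(tree4())
  sp <- spec_gamma()
  prior0 <- optima_prior(m_c = 0.3, m_mu = -0.2, v_c = 0, v_mu = 0)
  y <- c(0.1, -0.4, 0.2, 0.3, -0.1, 0, 0.5, -0.3)
  ll <- gene_loglik_phylo(y, div, sp, prior0)
  # direct evaluation with the optimum pinned
  A <- optima_design_matrix(sp$kind, div$n_tips)
  mu <- as.numeric(A %*% c(0.3, -0.2))
  V <- tip_covariance(div, sp)
  R <- chol(V)
  z <- backsolve(R, y - mu, transpose = TRUE)
  direct <- -0.5 * (8 * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
  expect_equal(ll, direct, tolerance = 1e-10)
})

test_that("single species, independent kind factorizes into univariate normals", {
  div1 <- structure(list(n_tips = 1L, tip_names = "A", tip_depth = 1,
                         d = matrix(0, 1, 1), dvals = 0,
                         didx = matrix(0L, 1, 1)), class = "divergence")
  sp <- coevo_model_spec("independent", 2, 0.5, 1, 0.8)
  prior <- optima_prior(0.1, -0.2, 0.3, 0.2)
  y <- c(0.4, -0.6)
  ll <- gene_loglik_phylo(y, div1, sp, prior)
  v1 <- 1 / (2 * 2) + 0.3; v2 <- 0.8^2 / (2 * 0.5) + 0.2
  direct <- dnorm(y[1], 0.1, sqrt(v1), log = TRUE) +
            dnorm(y[2], -0.2, sqrt(v2), log = TRUE)
  expect_equal(ll, direct, tolerance = 1e-10)
})

test_that("mixture likelihood reduces exactly at the boundaries", {
  set.seed(4)
  div <- divergence_structure(tree4())
  sp <- spec_gamma(); prior <- optima_prior(); wn <- white_noise_spec()
  Y <- matrix(rnorm(3 * 8, 0, 0.5), 3, 8)
  traits <- structure(list(gene_ids = paste0("g", 1:3),
                           species = tree4()$tip.label, Y = Y),
                      class = "trait_table")
  lp <- sapply(1:3, function(g) gene_loglik_phylo(Y[g, ], div, sp, prior))
  lw <- sapply(1:3, function(g) gene_loglik_whitenoise(Y[g, ], prior, wn, sp$kind))
  expect_equal(mixture_loglik(traits, div, sp, prior, wn, 0), sum(lp),
               tolerance = 1e-12)
  expect_equal(mixture_loglik(traits, div, sp, prior, wn, 1), sum(lw),
               tolerance = 1e-12)
  brute <- sum(log(0.5 * exp(lp) + 0.5 * exp(lw)))
  expect_equal(mixture_loglik(traits, div, sp, prior, wn, 0.5), brute,
               tolerance = 1e-12)
  expect_error(mixture_loglik(traits, div, sp, prior, wn, 1.2), "p_wn")
})

test_that("likelihood is invariant under consistent species reordering", {
  set.seed(8)
  cfg <- sim_config(n_genes = 20, seed = 14)
  sim <- simulate_traits(cfg)
  tr <- cfg$tree
  div <- divergence_structure(tr)
  ll <- mixture_loglik(sim$traits, div, cfg$spec, cfg$prior, cfg$wn, 0.149)
  perm <- c(4, 2, 6, 1, 3, 5)
  tr2 <- tr
  # permute by relabeling: swap tip labels and reorder trait columns to match
  relab <- tr$tip.label[perm]
  cols <- as.numeric(rbind(2 * perm - 1, 2 * perm))
  traits2 <- structure(list(gene_ids = sim$traits$gene_ids, species = relab,
                            Y = sim$traits$Y[, cols]), class = "trait_table")
  # rebuild divergence from the same tree with tips listed in the new order
  d2 <- div$d[perm, perm]
  dvals2 <- unique(as.vector(d2))
  div2 <- structure(list(n_tips = 6L, tip_names = relab, tip_depth = div$tip_depth,
                         d = d2, dvals = dvals2,
                         didx = matrix(match(d2, dvals2) - 1L, 6, 6)),
                    class = "divergence")
  ll2 <- mixture_loglik(traits2, div2, cfg$spec, cfg$prior, cfg$wn, 0.149)
  expect_equal(ll2, ll, tolerance = 1e-9)
})

test_that("fitting returns an honest, AIC-consistent result on tiny input", {
  set.seed(2)
  Y <- matrix(rnorm(4), 2, 4)
  traits <- structure(list(gene_ids = c("g1", "g2"), species = c("A", "B"), Y = Y),
                      class = "trait_table")
  tr <- read_tree("(A:1,B:1);")
  f <- fit_mixture(traits, tr, "independent", n_starts = 2, seed = 1, maxit = 50)
  expect_true(is.finite(f$loglik))
  expect_true(is.logical(f$converged))
  expect_equal(f$aic, 2 * f$n_params - 2 * f$loglik, tolerance = 1e-12)
  expect_true(all(f$posterior_wn >= 0 & f$posterior_wn <= 1))
})

test_that("AIC identity and fixed prior means reduce the parameter count", {
  set.seed(3)
  cfg <- sim_config(n_genes = 40, seed = 5)
  sim <- simulate_traits(cfg)
  f <- fit_mixture(sim$traits, cfg$tree, "gamma_constrained", n_starts = 2, seed = 2)
  expect_identical(f$n_params, 11L)
  expect_equal(f$aic, 2 * 11 - 2 * f$loglik, tolerance = 1e-12)
  f9 <- fit_mixture(sim$traits, cfg$tree, "gamma_constrained", n_starts = 2,
                    fix_prior_means = TRUE, seed = 2)
  expect_identical(f9$n_params, 9L)
  expect_equal(f9$prior$m_c, 0)
})

test_that("compare_models ranks by AIC and validates shared data", {
  mk <- function(kind, k, ll, fp) {
    structure(list(kind = kind, n_params = k, loglik = ll, aic = 2 * k - 2 * ll,
                   fingerprint = fp), class = "mixture_fit")
  }
  fp <- c(n_genes = 5, n_species = 4, sum = 1, sumsq = 2)
  tb <- compare_models(list(mk("a", 3, -10, fp), mk("b", 3, -12, fp)))
  expect_equal(tb$aic[1], 26)
  expect_equal(tb$model, c("a", "b"))
  expect_equal(tb$delta_aic, c(0, 4))
  fp2 <- fp; fp2["sum"] <- 99
  expect_error(compare_models(list(mk("a", 3, -10, fp), mk("b", 3, -12, fp2))),
               "identical data")
})

test_that("posterior white-noise probabilities behave at boundaries and separate labels", {
  set.seed(6)
  cfg <- sim_config(n_genes = 300, p_wn = 0.3, seed = 33)
  sim <- simulate_traits(cfg)
  div <- divergence_structure(cfg$tree)
  mkfit <- function(p) {
    structure(list(kind = cfg$spec$kind, spec = cfg$spec, prior = cfg$prior,
                   wn = cfg$wn, p_wn = p), class = "mixture_fit")
  }
  expect_true(all(posterior_wn_probs(mkfit(0), sim$traits, div) == 0))
  expect_true(all(posterior_wn_probs(mkfit(1), sim$traits, div) == 1))
  post <- posterior_wn_probs(mkfit(0.3), sim$traits, div)
  expect_true(all(post >= 0 & post <= 1))
  is_wn <- sim$labels == "wn"
  expect_gt(median(post[is_wn]), median(post[!is_wn]))
  # AUC of the separation under the true parameters
  r <- rank(post)
  auc <- (sum(r[is_wn]) - sum(is_wn) * (sum(is_wn) + 1) / 2) /
         (sum(is_wn) * sum(!is_wn))
  expect_gt(auc, 0.8)
})

test_that("expression binning follows the outer-remainder tercile convention", {
  expect_equal(phyloburst:::bin_sizes(167, 3), c(56, 55, 56))
  expect_equal(phyloburst:::bin_sizes(6, 3), c(2, 2, 2))
  expect_equal(phyloburst:::bin_sizes(7, 3), c(3, 2, 2))
  set.seed(10)
  cfg <- sim_config(n_genes = 167, seed = 9)
  sim <- simulate_traits(cfg)
  cov <- setNames(rnorm(167), sim$traits$gene_ids)
  bb <- fit_by_bins(sim$traits, cfg$tree, "gamma_constrained", cov,
                    n_starts = 2, seed = 4, maxit = 60)
  expect_equal(bb$sizes, c(56, 55, 56))
  expect_equal(length(bb$fits), 3L)
  # membership equals a rank-based split for a monotone covariate
  ord <- order(cov, seq_along(cov))
  expect_true(all(bb$bins[ord] == rep(1:3, times = c(56, 55, 56))))
  expect_error(fit_by_bins(sim$traits, cfg$tree, "gamma_constrained",
                           cov, n_bins = 100), "fewer than 2")
})
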