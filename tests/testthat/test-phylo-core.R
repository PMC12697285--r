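test_that("read_tree parses, validates and measures simple trees", {
  tr <- read_tree("(A:1,B:1);")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(attr(tr, "tip_depth"), 1)
  d <- divergence_structure(tr)$d
  expect_equal(d["A", "B"], 1)

  tr2 <- read_tree("((A:1,B:1):1,C:2);")
  d2 <- divergence_structure(tr2)$d
  expect_equal(d2["A", "B"], 1)
  expect_equal(d2["A", "C"], 2)
  expect_equal(d2["B", "C"], 2)

  expect_error(read_tree("((A:1,B:2):1,C:2);"), "ultrametric")
  expect_silent(read_tree("((A:1,B:2):1,C:2);", allow_nonultrametric = TRUE))
  expect_error(read_tree("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(read_tree("(A:1,B:-1);"), "negative")
})

test_that("divergence structure matches a brute-force tree walk", {
  # 6-tip caterpillar with unit internal edges
  nwk <- "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5);"
  tr <- read_tree(nwk)
  div <- divergence_structure(tr)
  bf <- brute_force_d(tr)
  expect_equal(div$d[rownames(bf), colnames(bf)], bf, tolerance = 1e-12)
  # symmetry, range, and the ultrametric three-point condition
  expect_equal(div$d, t(div$d))
  expect_true(all(div$d >= 0 & div$d <= div$tip_depth + 1e-12))
  n <- div$n_tips
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    trio <- sort(c(div$d[i, j], div$d[i, k], div$d[j, k]), decreasing = TRUE)
    expect_equal(trio[1], trio[2], tolerance = 1e-9)
  }
})

test_that("selection matrices have the three constraint structures", {
  H <- selection_matrix(spec_gamma())
  expect_equal(unname(H), matrix(c(31.5, 0, -31.5, 2.33), 2, 2))
  H2 <- selection_matrix(spec_b())
  expect_equal(unname(H2), matrix(c(0.022, -3.56, 0, 3.56), 2, 2))
  H3 <- selection_matrix(coevo_model_spec("independent", 1, 1, 1, 1))
  expect_equal(unname(H3), diag(2))
  # eigenvalues are always the two selection rates
  for (sp in list(spec_gamma(), spec_b(), spec_indep())) {
    ev <- sort(eigen(selection_matrix(sp))$values)
    expect_equal(ev, sort(c(sp$alpha_b, sp$alpha_gamma)), tolerance = 1e-12)
  }
  expect_error(coevo_model_spec("independent", -1, 1, 1, 1), "> 0")
})

test_that("stationary covariance solves the Lyapunov equation", {
  V <- stationary_covariance(coevo_model_spec("independent", 1, 1, sqrt(2), sqrt(2)))
  expect_equal(unname(V), diag(2), tolerance = 1e-12)
  set.seed(71)
  for (i in 1:50) {
    kind <- sample(c("gamma_constrained", "b_constrained", "independent"), 1)
    sp <- coevo_model_spec(kind, exp(runif(1, log(0.01), log(100))),
                           exp(runif(1, log(0.01), log(100))),
                           exp(runif(1, log(0.1), log(10))),
                           exp(runif(1, log(0.1), log(10))))
    H <- selection_matrix(sp); V <- stationary_covariance(sp)
    Q <- diag(c(sp$sigma_b^2, sp$sigma_gamma^2))
    resid <- H %*% V + V %*% t(H) - Q
    expect_lt(max(abs(resid)) / max(abs(Q)), 1e-10)
    expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("stationary covariance matches an Euler-Maruyama ensemble", {
  set.seed(21)
  sp <- spec_gamma()
  X <- em_paths(sp, x0 = c(0, 0), xhat = c(0, 0), t = 3 / min(sp$alpha_b, sp$alpha_gamma),
                n_paths = 6000, dt = 5e-4)
  V <- stationary_covariance(sp)
  Vemp <- cov(X)
  se <- sqrt((diag(V) %o% diag(V) + V^2) / 6000)   # asymptotic cov-entry SE
  expect_true(all(abs(Vemp - V) < 4 * se))
})

test_that("OU transition has exact endpoints and closed univariate form", {
  sp <- coevo_model_spec("independent", 1, 1, sqrt(2), sqrt(2))
  tr0 <- ou_transition(sp, x0 = c(1, 0), xhat = c(0, 0), t = 0)
  expect_equal(tr0$mean, c(1, 0))
  expect_equal(unname(tr0$cov), matrix(0, 2, 2))
  tr1 <- ou_transition(sp, x0 = c(1, 0), xhat = c(0, 0), t = 1)
  expect_equal(tr1$mean, c(exp(-1), 0), tolerance = 1e-12)
  expect_equal(unname(diag(tr1$cov)), rep(1 - exp(-2), 2), tolerance = 1e-12)
  trInf <- ou_transition(sp, x0 = c(1, 0), xhat = c(0.3, -0.2), t = 200)
  expect_equal(trInf$mean, c(0.3, -0.2), tolerance = 1e-10)
  expect_equal(trInf$cov, stationary_covariance(sp), tolerance = 1e-10)
  expect_error(ou_transition(sp, c(0, 0), c(0, 0), -1), "negative")
})

test_that("OU transition matches Euler-Maruyama moments for the coupled model", {
  set.seed(31)
  sp <- spec_gamma()
  x0 <- c(1, -0.5); xhat <- c(0.2, 0.1); tt <- 0.5
  n <- 30000
  X <- em_paths(sp, x0, xhat, tt, n, dt = 2.5e-4)
  ex <- ou_transition(sp, x0, xhat, tt)
  se_mean <- sqrt(diag(ex$cov) / n)
  expect_true(all(abs(colMeans(X) - ex$mean) < 4 * se_mean))
  se_cov <- sqrt((diag(ex$cov) %o% diag(ex$cov) + ex$cov^2) / n)
  expect_true(all(abs(cov(X) - ex$cov) < 4 * se_cov + 2e-3))
})

test_that("transition covariance is PSD and Loewner-increasing in time", {
  for (sp in list(spec_gamma(), spec_b(), spec_indep())) {
    prev <- matrix(0, 2, 2)
    for (tt in c(0.02, 0.1, 0.3, 0.8, 2, 5)) {
      cv <- ou_transition(sp, c(0, 0), c(0, 0), tt)$cov
      expect_true(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) > -1e-12)
      expect_true(min(eigen(cv - prev, symmetric = TRUE,
                            only.values = TRUE)$values) > -1e-10)
      prev <- cv
    }
  }
})

test_that("tip covariance blocks follow the closed forms", {
  sp <- coevo_model_spec("independent", 1, 1, sqrt(2), sqrt(2))
  tr <- read_tree("(A:1,B:1);")
  V <- tip_covariance(divergence_structure(tr), sp)
  expect_equal(V[1, 3], exp(-2), tolerance = 1e-12)   # sigma^2/(2 alpha) e^{-2 alpha d}
  expect_equal(V[2, 4], exp(-2), tolerance = 1e-12)
  expect_equal(V[1, 4], 0)
  expect_equal(V[1:2, 1:2], unname(stationary_covariance(sp)), tolerance = 1e-14)

  # independent kind == composition of two univariate OU tree covariances
  sp2 <- spec_indep()
  div <- divergence_structure(tree4())
  V2 <- tip_covariance(div, sp2)
  n <- div$n_tips
  for (trait in 1:2) {
    a <- if (trait == 1) sp2$alpha_b else sp2$alpha_gamma
    s <- if (trait == 1) sp2$sigma_b else sp2$sigma_gamma
    uni <- s^2 / (2 * a) * exp(-2 * a * div$d)
    idx <- seq(trait, 2 * n, 2)
    expect_equal(unname(V2[idx, idx]), unname(uni), tolerance = 1e-12)
  }
  # cross-trait blocks vanish for the independent kind
  expect_equal(max(abs(V2[seq(1, 2 * n, 2), seq(2, 2 * n, 2)])), 0)
})

test_that("tip covariance approaches the white-noise limit at large selection", {
  div <- divergence_structure(tree4())
  sp <- coevo_model_spec("gamma_constrained", 500, 400, 1, 1)
  V <- tip_covariance(div, sp)
  Vinf <- stationary_covariance(sp)
  off <- V
  for (i in seq_len(div$n_tips)) off[(2 * i - 1):(2 * i), (2 * i - 1):(2 * i)] <- 0
  expect_lt(max(abs(off)) / max(abs(Vinf)), 1e-6)
})

test_that("tip covariance matches trait simulation for all three kinds", {
  div <- divergence_structure(tree4())
  for (sp in list(spec_gamma(), spec_b(), spec_indep())) {
    cfg <- sim_config(tree = tree4(), spec = sp,
                      prior = optima_prior(0, 0, 0, 0),   # fixed optima at 0
                      p_wn = 0, n_genes = 8000, seed = 17)
    sim <- simulate_traits(cfg)
    Vemp <- cov(sim$traits$Y)
    V <- tip_covariance(div, sp)
    se <- sqrt((diag(V) %o% diag(V) + V^2) / 8000)
    expect_true(all(abs(Vemp - V) < 4 * se))
  }
})

test_that("fixed-root convention reduces covariance near the root and at d = T", {
  div <- divergence_structure(tree4())
  sp <- spec_gamma()
  Vs <- tip_covariance(div, sp, root = "stationary")
  Vf <- tip_covariance(div, sp, root = "fixed")
  # deepest split (d = T): fixed-root covariance between the two sides is 0
  i <- 1; j <- div$n_tips   # A vs D, d = 1 = tree height
  expect_equal(max(abs(Vf[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])), 0,
               tolerance = 1e-12)
  expect_gt(abs(Vs[2 * i, 2 * j]), 0)
})

test_that("optima design matrices map optima to stationary means", {
  A <- optima_design_matrix("gamma_constrained", 1)
  expect_equal(as.numeric(A %*% c(0.5, 1.2)), c(1.7, 0.5))
  A2 <- optima_design_matrix("b_constrained", 1)
  expect_equal(as.numeric(A2 %*% c(1.0, 0.3)), c(1.0, 0.7))
  A3 <- optima_design_matrix("independent", 3)
  expect_equal(dim(A3), c(6, 2))
  # A theta is a drift fixed point for every kind: H (A theta - Xhat) = 0
  set.seed(5)
  for (sp in list(spec_gamma(), spec_b(), spec_indep())) {
    H <- selection_matrix(sp)
    B <- optima_design_matrix(sp$kind, 1)
    for (r in 1:5) {
      theta <- rnorm(2)
      xhat <- as.numeric(B %*% theta)
      expect_equal(as.numeric(H %*% (xhat - xhat)), c(0, 0))
      # and the OU transition converges to that mean
      t_long <- 30 / min(sp$alpha_b, sp$alpha_gamma)
      expect_equal(ou_transition(sp, rnorm(2), xhat, t_long)$mean, xhat,
                   tolerance = 1e-8)
    }
  }
})
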