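# Shared fixtures and independent oracles for the test suite. Oracles here
# deliberately avoid the package's own code paths: brute-force tree walks,
# Euler-Maruyama SDE integration, Monte-Carlo prior integration, explicit
# Poisson convolution.

spec_gamma <- function() coevo_model_spec("gamma_constrained", 31.5, 2.33, 0.923, 1.06)
spec_b     <- function() coevo_model_spec("b_constrained", 0.022, 3.56, 3.01, 0.169)
spec_indep <- function() coevo_model_spec("independent", 1.36, 1.59, 0.651, 0.831)

tree4 <- function() read_tree("(((A:0.2,B:0.2):0.3,C:0.5):0.5,D:1);")

# brute-force tip divergence: walk each tip's ancestor path along tr$edge,
# find the MRCA as the deepest shared ancestor, return its depth distance
brute_force_d <- function(tr) {
  n <- length(tr$tip.label)
  root <- n + 1L
  parent_of <- integer(max(tr$edge))
  elen_of <- numeric(max(tr$edge))
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  elen_of[tr$edge[, 2]] <- tr$edge.length
  path_up <- function(tip) {
    nodes <- tip; node <- tip
    while (node != root) { node <- parent_of[node]; nodes <- c(nodes, node) }
    nodes
  }
  depth_of <- function(node) {
    dsum <- 0
    while (node != root) { dsum <- dsum + elen_of[node]; node <- parent_of[node] }
    dsum
  }
  d <- matrix(0, n, n, dimnames = list(tr$tip.label, tr$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      anc_i <- path_up(i); anc_j <- path_up(j)
      mrca <- anc_i[which(anc_i %in% anc_j)[1]]
      d[i, j] <- depth_of(i) - depth_of(mrca)
    }
  }
  d
}

# Euler-Maruyama ensemble of the OU SDE; returns n_paths x 2 states at time t
em_paths <- function(spec, x0, xhat, t, n_paths, dt = 1e-3) {
  H <- selection_matrix(spec)
  S <- diag(c(spec$sigma_b, spec$sigma_gamma))
  X <- matrix(rep(x0, each = n_paths), n_paths, 2)
  n_steps <- ceiling(t / dt)
  dt <- t / n_steps
  sq <- sqrt(dt)
  for (k in seq_len(n_steps)) {
    drift <- -(sweep(X, 2, xhat)) %*% t(H)
    X <- X + dt * drift + sq * matrix(rnorm(2 * n_paths), n_paths, 2) %*% t(S)
  }
  X
}

# Monte-Carlo marginalization oracle: E_theta[ N(y; A theta, V) ] by direct
# averaging over prior draws
mc_marginal_loglik <- function(y, V, A, prior, n_draws = 2e5) {
  th <- rbind(prior$m_c + sqrt(prior$v_c) * rnorm(n_draws),
              prior$m_mu + sqrt(prior$v_mu) * rnorm(n_draws))
  mu <- A %*% th                       # 2n x n_draws
  R <- chol(V)
  Z <- backsolve(R, matrix(y, length(y), n_draws) - mu, transpose = TRUE)
  logdens <- -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(Z^2))
  m <- max(logdens)
  m + log(mean(exp(logdens - m)))
}

# stationary Gillespie moments helper
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
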