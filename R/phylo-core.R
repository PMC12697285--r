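#' Read and validate an ultrametric phylogeny
#'
#' Parses a newick string into an [ape::phylo] tree and checks the invariants
#' the coevolution models rely on: branch lengths present and nonnegative,
#' unique tip labels, and ultrametricity (equal root-to-tip depths) within a
#' relative tolerance. Multifurcating trees are accepted; only divergence
#' times matter downstream.
#'
#' @param newick_text Newick string (or a file path when `file = TRUE`).
#' @param tol Relative ultrametricity tolerance on root-to-tip depths.
#' @param allow_nonultrametric If `TRUE`, depth inequality is tolerated and
#'   per-tip depths are kept as-is; default `FALSE` (error).
#' @param file Treat `newick_text` as a path.
#' @return An object of class `phylo` with an added `"tip_depth"` attribute.
#' @export
read_tree <- function(newick_text, tol = 1e-6, allow_nonultrametric = FALSE,
                      file = FALSE) {
  tr <- if (file) ape::read.tree(newick_text) else ape::read.tree(text = newick_text)
  if (is.null(tr)) stop("failed to parse newick input")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tr$edge.length)) stop("tree has missing branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip names")
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  T0 <- max(depths)
  if (T0 > 0 && diff(range(depths)) > tol * T0 && !allow_nonultrametric) {
    stop(sprintf("tree is not ultrametric: tip depths range [%.8g, %.8g]",
                 min(depths), max(depths)))
  }
  attr(tr, "tip_depth") <- T0
  tr
}

#' Divergence structure of an ultrametric tree
#'
#' Caches the geometry needed for OU covariance assembly: the number of tips,
#' the root-to-tip depth T, and the matrix `d` where `d[i, j]` is the time
#' from the most recent common ancestor of tips i and j back to either tip
#' (equal for both tips by ultrametricity), with zero diagonal.
#'
#' @param tree A `phylo` tree (ideally from [read_tree()]).
#' @return A list of class `divergence` with elements `n_tips`, `tip_names`,
#'   `tip_depth`, and `d`.
#' @export
divergence_structure <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # patristic distance between two tips of an ultrametric tree is twice the
  # MRCA-to-tip time
  d <- ape::cophenetic.phylo(tree) / 2
  d <- d[tree$tip.label, tree$tip.label, drop = FALSE]
  diag(d) <- 0
  T0 <- attr(tree, "tip_depth")
  if (is.null(T0)) T0 <- max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  n <- length(tree$tip.label)
  dvals <- unique(as.vector(d))
  structure(list(n_tips = n, tip_names = tree$tip.label,
                 tip_depth = T0, d = d, dvals = dvals,
                 didx = matrix(match(d, dvals) - 1L, n, n)),
            class = "divergence")
}

#' Specify a coevolution model
#'
#' Bundles the selection and diffusion parameters of the bivariate
#' Ornstein-Uhlenbeck process on `(log b, log gamma)`. Three constraint
#' structures are supported:
#' \describe{
#'   \item{`gamma_constrained`}{stabilizing selection acts directly on the log
#'     decay rate and on log mean expression; burst size adapts.}
#'   \item{`b_constrained`}{selection acts directly on log burst size and on
#'     log mean expression; the decay rate adapts.}
#'   \item{`independent`}{each trait reverts to its own optimum with no
#'     coupling.}
#' }
#'
#' @param kind One of `"gamma_constrained"`, `"b_constrained"`, `"independent"`.
#' @param alpha_b,alpha_gamma Selection rates (per unit branch length), > 0.
#' @param sigma_b,sigma_gamma Diffusion scales (trait units per sqrt(time)), > 0.
#' @return A list of class `coevo_spec`.
#' @export
coevo_model_spec <- function(kind = c("gamma_constrained", "b_constrained",
                                      "independent"),
                             alpha_b, alpha_gamma, sigma_b, sigma_gamma) {
  kind <- match.arg(kind)
  vals <- c(alpha_b = alpha_b, alpha_gamma = alpha_gamma,
            sigma_b = sigma_b, sigma_gamma = sigma_gamma)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("alpha_b, alpha_gamma, sigma_b, sigma_gamma must all be finite and > 0")
  }
  structure(list(kind = kind, alpha_b = alpha_b, alpha_gamma = alpha_gamma,
                 sigma_b = sigma_b, sigma_gamma = sigma_gamma),
            class = "coevo_spec")
}

#' @export
print.coevo_spec <- function(x, ...) {
  cat(sprintf("coevolution model [%s]\n", x$kind))
  cat(sprintf("  alpha_b = %g, alpha_gamma = %g\n", x$alpha_b, x$alpha_gamma))
  cat(sprintf("  sigma_b = %g, sigma_gamma = %g\n", x$sigma_b, x$sigma_gamma))
  invisible(x)
}

#' Selection matrix H of a coevolution model
#'
#' The drift of the trait process is `-H (X - Xhat)`. The triangular structure
#' of H encodes which biophysical parameter is directly constrained: in the
#' decay-rate-constrained model the burst-size coordinate is pulled toward
#' whatever value restores the optimal log mean expression
#' (`log mu = log b - log gamma`), while `log gamma` reverts on its own;
#' the burst-size-constrained model is the mirror image; the independent model
#' is diagonal. Eigenvalues are always `{alpha_b, alpha_gamma}`.
#'
#' @param spec A [coevo_model_spec()].
#' @return A 2x2 numeric matrix, rows/cols ordered `(log b, log gamma)`.
#' @export
selection_matrix <- function(spec) {
  stopifnot(inherits(spec, "coevo_spec"))
  ab <- spec$alpha_b; ag <- spec$alpha_gamma
  H <- switch(spec$kind,
    gamma_constrained = matrix(c(ab, 0, -ab, ag), 2, 2),
    b_constrained     = matrix(c(ab, -ag, 0, ag), 2, 2),
    independent       = diag(c(ab, ag))
  )
  dimnames(H) <- list(c("log_b", "log_gamma"), c("log_b", "log_gamma"))
  H
}

diffusion_matrix <- function(spec) diag(c(spec$sigma_b, spec$sigma_gamma))

#' Stationary covariance of the coevolution OU process
#'
#' Solves the continuous Lyapunov equation `H V + V H' = Sigma Sigma'` with
#' `Sigma = diag(sigma_b, sigma_gamma)` via the vectorized linear system.
#'
#' @param spec A [coevo_model_spec()].
#' @return Symmetric positive-definite 2x2 matrix.
#' @export
stationary_covariance <- function(spec) {
  H <- selection_matrix(spec)
  q11 <- spec$sigma_b^2; q22 <- spec$sigma_gamma^2
  # symmetric V = [[v1, v2], [v2, v3]]: the Lyapunov equation reduces to a
  # 3x3 linear system in (v1, v2, v3)
  M <- rbind(c(2 * H[1, 1], 2 * H[1, 2], 0),
             c(H[2, 1], H[1, 1] + H[2, 2], H[1, 2]),
             c(0, 2 * H[2, 1], 2 * H[2, 2]))
  v <- tryCatch(solve(M, c(q11, 0, q22)),
                error = function(e) stop("singular Lyapunov system: ", conditionMessage(e)))
  V <- matrix(c(v[1], v[2], v[2], v[3]), 2, 2)
  if (any(diag(V) <= 0)) stop("stationary covariance is not positive definite")
  dimnames(V) <- dimnames(H)
  V
}

# Exact exponential of a real 2x2 matrix via the trace/determinant closed form
# e^M = e^{m} [cosh(q) I + sinh(q)/q (M - m I)], m = tr(M)/2, q^2 = m^2 - det(M).
# Uniformly valid (q -> 0 and imaginary q handled by cos/sinc), so the
# alpha_b == alpha_gamma case needs no special-casing.
expm2 <- function(M) {
  m <- (M[1, 1] + M[2, 2]) / 2
  q2 <- m * m - (M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
  if (q2 >= 0) {
    q <- sqrt(q2)
    # e^m cosh(q), e^m sinh(q)/q evaluated as exp(m +/- q) to avoid overflow
    # of cosh at large |q| (relevant for strong selection x long branches)
    ep <- exp(m + q); en <- exp(m - q)
    ch <- (ep + en) / 2
    sh_over_q <- if (q < 1e-8) exp(m) * (1 + q2 / 6) else (ep - en) / (2 * q)
  } else {
    q <- sqrt(-q2)
    ch <- exp(m) * cos(q)
    sh_over_q <- exp(m) * (if (q < 1e-8) 1 - q * q / 6 else sin(q) / q)
  }
  ch * diag(2) + sh_over_q * (M - m * diag(2))
}

#' Exact Gaussian transition of the coevolution OU process
#'
#' For the linear SDE `dX = -H (X - Xhat) dt + Sigma dW`, the time-t
#' transition is Gaussian with mean `Xhat + e^{-Ht}(x0 - Xhat)` and covariance
#' `Vinf - e^{-Ht} Vinf e^{-H't}`.
#'
#' @param spec A [coevo_model_spec()].
#' @param x0 Numeric length-2 start state `(log b, log gamma)`.
#' @param xhat Numeric length-2 optimum.
#' @param t Nonnegative elapsed time.
#' @return List with `mean` (length 2) and `cov` (2x2).
#' @export
ou_transition <- function(spec, x0, xhat, t) {
  if (t < 0) stop("negative time")
  H <- selection_matrix(spec)
  Vinf <- stationary_covariance(spec)
  E <- expm2(-H * t)
  mean <- as.numeric(xhat + E %*% (x0 - xhat))
  cov <- Vinf - E %*% Vinf %*% t(E)
  cov <- (cov + t(cov)) / 2
  list(mean = mean, cov = cov)
}

#' Joint tip covariance of the stationary OU process on a tree
#'
#' Under the stationary-root convention (root drawn from the stationary law
#' centered at the gene's optimum), the covariance between the trait vectors
#' of tips i and j is `e^{-H d[i,j]} Vinf e^{-H' d[i,j]}`, where `d[i,j]` is
#' the MRCA-to-tip time. Traits are stacked species-major interleaved:
#' `(b_1, gamma_1, b_2, gamma_2, ...)`.
#'
#' With `root = "fixed"` the root is instead pinned at the optimum and the
#' non-stationary transition covariance is used:
#' `Cov(X_i, X_j) = e^{-H d} V(T - d) e^{-H' d}` with `V(t)` the transition
#' covariance over the root-to-MRCA time `T - d`.
#'
#' @param div A [divergence_structure()].
#' @param spec A [coevo_model_spec()].
#' @param root `"stationary"` (default) or `"fixed"`.
#' @return A `2n x 2n` symmetric positive-semidefinite matrix.
#' @export
tip_covariance <- function(div, spec, root = c("stationary", "fixed"),
                           check_psd = TRUE) {
  root <- match.arg(root)
  stopifnot(inherits(div, "divergence"))
  H <- selection_matrix(spec)
  Vinf <- stationary_covariance(spec)
  n <- div$n_tips
  # pair blocks depend on d only; compute one block per unique divergence time
  dvals <- unique(as.vector(div$d))
  blocks <- lapply(dvals, function(dd) {
    E <- expm2(-H * dd)
    Vm <- if (root == "stationary") Vinf else {
      tau <- div$tip_depth - dd       # root-to-MRCA elapsed time
      Et <- expm2(-H * tau)
      Vinf - Et %*% Vinf %*% t(Et)
    }
    E %*% Vm %*% t(E)
  })
  V <- matrix(0, 2 * n, 2 * n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      blk <- blocks[[match(div$d[i, j], dvals)]]
      ri <- (2 * i - 1):(2 * i); rj <- (2 * j - 1):(2 * j)
      V[ri, rj] <- blk
      if (i != j) V[rj, ri] <- t(blk)
    }
  }
  V <- (V + t(V)) / 2
  if (check_psd) {
    ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8 * max(abs(diag(V)))) {
      stop("tip covariance is not positive semidefinite (numerical failure)")
    }
  }
  V
}

#' Design matrix mapping optima to stationary tip means
#'
#' Each model's stationary trait mean is a linear map of the gene-level optima
#' `theta = (theta_c, theta_mu)`, where `theta_c` is the optimum of the
#' directly constrained coordinate and `theta_mu` the optimal log mean spliced
#' expression. Per-species 2x2 blocks:
#' gamma-constrained `[[1, 1], [1, 0]]` (mean `(theta_gamma + theta_mu,
#' theta_gamma)`); b-constrained `[[1, 0], [1, -1]]` (mean `(theta_b,
#' theta_b - theta_mu)`); independent: identity with `theta = (theta_b,
#' theta_gamma)`. The block is replicated down all species.
#'
#' @param kind Model kind string.
#' @param n_tips Number of species.
#' @return A `2 n_tips x 2` matrix.
#' @export
optima_design_matrix <- function(kind, n_tips) {
  stopifnot(n_tips >= 1)
  B <- switch(match.arg(kind, c("gamma_constrained", "b_constrained", "independent")),
    gamma_constrained = matrix(c(1, 1, 1, 0), 2, 2),
    b_constrained     = matrix(c(1, 1, 0, -1), 2, 2),
    independent       = diag(2)
  )
  kronecker(matrix(1, n_tips, 1), B)
}
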