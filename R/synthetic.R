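#' Default study tree
#'
#' A six-tip ultrametric tree of unit height with a mix of shallow and deep
#' splits, standing in for a time-calibrated vertebrate phylogeny with branch
#' lengths rescaled to tree height 1 (selection and diffusion rates are then
#' per tree height).
#'
#' @return A `phylo` tree from [read_tree()].
#' @export
default_study_tree <- function() {
  read_tree("((((sp1:0.1,sp2:0.1):0.15,sp3:0.25):0.35,(sp4:0.3,sp5:0.3):0.3):0.4,sp6:1);")
}

#' Simulation configuration
#'
#' Bundles everything the generators need: tree, coevolution model, optima
#' prior, white-noise component, mixture weight, gene/cell numbers, technical
#' noise and the master seed.
#'
#' @param tree A `phylo` tree.
#' @param spec A [coevo_model_spec()].
#' @param prior An [optima_prior()].
#' @param wn A [white_noise_spec()].
#' @param p_wn White-noise mixture weight.
#' @param n_genes Number of genes.
#' @param cells_per_species Cells simulated per species.
#' @param lambda_u,lambda_s Optional Poisson technical-noise intensities.
#' @param log_beta_mean,log_beta_sd Splicing-rate log-normal: beta carries no
#'   evolutionary signal in the trait model (log mean expression is
#'   independent of it) but the count simulator needs a value, so it is drawn
#'   iid per gene and species.
#' @param covariate_sd Gaussian noise (log scale) added to the expression
#'   covariate, emulating a cross-dataset expression estimate.
#' @param seed Master seed; all substreams derive from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(tree = default_study_tree(),
                       spec = coevo_model_spec("gamma_constrained",
                                               alpha_b = 31.5, alpha_gamma = 2.33,
                                               sigma_b = 0.923, sigma_gamma = 1.06),
                       prior = optima_prior(),
                       wn = white_noise_spec(),
                       p_wn = 0.149,
                       n_genes = 167, cells_per_species = 1000,
                       lambda_u = NULL, lambda_s = NULL,
                       log_beta_mean = 0, log_beta_sd = 0.5,
                       covariate_sd = 0.3, seed = 1) {
  stopifnot(n_genes >= 1, cells_per_species >= 1, p_wn >= 0, p_wn <= 1)
  structure(list(tree = tree, spec = spec, prior = prior, wn = wn, p_wn = p_wn,
                 n_genes = n_genes, cells_per_species = cells_per_species,
                 lambda_u = lambda_u, lambda_s = lambda_s,
                 log_beta_mean = log_beta_mean, log_beta_sd = log_beta_sd,
                 covariate_sd = covariate_sd, seed = seed),
            class = "sim_config")
}

rmvnorm2 <- function(n, mean, V) {
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(V))
  t(mean + L %*% matrix(rnorm(n * nrow(V)), nrow(V), n))
}

#' Simulate trait histories along the tree under the mixture model
#'
#' For every gene: a component label is drawn (white-noise with probability
#' `p_wn`); gene optima `theta` are drawn from the prior and mapped to the
#' stationary mean. Phylogenetic genes start the root at the stationary law
#' `N(Xhat, Vinf)` and recurse down the tree with exact OU transition
#' sampling; white-noise genes draw species-iid residuals around the mean.
#'
#' @param config A [sim_config()].
#' @return List with `traits` (a [trait_table()]), `labels`
#'   (`"phylo"`/`"wn"`), and `optima` (genes x 2 matrix of `(theta_c,
#'   theta_mu)`).
#' @export
simulate_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$tree; spec <- config$spec
  n <- length(tr$tip.label)
  set.seed(config$seed)
  H <- selection_matrix(spec)
  Vinf <- stationary_covariance(spec)
  B <- optima_design_matrix(spec$kind, 1)
  G <- config$n_genes
  labels <- ifelse(runif(G) < config$p_wn, "wn", "phylo")
  theta <- cbind(config$prior$m_c + sqrt(config$prior$v_c) * rnorm(G),
                 config$prior$m_mu + sqrt(config$prior$v_mu) * rnorm(G))
  colnames(theta) <- c("theta_c", "theta_mu")
  Y <- matrix(NA_real_, G, 2 * n)
  # preorder edge traversal; node states held in a list indexed by node id
  root <- n + 1L
  pre <- reorder(tr, "postorder")
  edge_pre <- pre$edge[rev(seq_len(nrow(pre$edge))), , drop = FALSE]
  elen_pre <- pre$edge.length[rev(seq_len(nrow(pre$edge)))]
  Dwn <- diag(c(config$wn$v_wn_b, config$wn$v_wn_gamma))
  for (g in seq_len(G)) {
    xhat <- as.numeric(B %*% theta[g, ])
    if (labels[g] == "wn") {
      Y[g, ] <- as.numeric(t(rmvnorm2(n, xhat, Dwn)))
    } else {
      states <- vector("list", max(tr$edge))
      states[[root]] <- as.numeric(rmvnorm2(1, xhat, Vinf))
      for (e in seq_len(nrow(edge_pre))) {
        par <- edge_pre[e, 1]; child <- edge_pre[e, 2]
        tlen <- elen_pre[e]
        if (tlen == 0) {
          states[[child]] <- states[[par]]
        } else {
          E <- expm2(-H * tlen)
          mu <- xhat + as.numeric(E %*% (states[[par]] - xhat))
          Vt <- Vinf - E %*% Vinf %*% t(E)
          states[[child]] <- as.numeric(rmvnorm2(1, mu, Vt))
        }
      }
      for (si in seq_len(n)) Y[g, (2 * si - 1):(2 * si)] <- states[[si]]
    }
  }
  gene_ids <- sprintf("g%04d", seq_len(G))
  rownames(Y) <- gene_ids
  colnames(Y) <- paste(rep(tr$tip.label, each = 2), c("log_b", "log_gamma"), sep = ".")
  traits <- structure(list(gene_ids = gene_ids, species = tr$tip.label, Y = Y),
                      class = "trait_table")
  list(traits = traits, labels = labels, optima = theta)
}

#' Draw stationary cells from the bursty model
#'
#' Independent Gillespie trajectories (one per cell) from the empty state,
#' burned in for `20 / min(beta, gamma)` time units, then observed once.
#' Optional Poisson technical noise thins/overdraws the true counts.
#'
#' @param params A [kinetic_params()].
#' @param n_cells Number of cells.
#' @param seed Optional integer seed (`NULL`: use the current RNG stream).
#' @param burnin_factor Burn-in is `burnin_factor / min(beta, gamma)`.
#' @return List with integer vectors `u`, `s`.
#' @export
simulate_counts <- function(params, n_cells, seed = NULL, burnin_factor = 20) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.null(seed)) set.seed(seed)
  burnin <- burnin_factor / min(params$beta, params$gamma)
  m <- gillespie_counts_cpp(n_cells, params$b, params$beta, params$gamma, burnin)
  u <- m[, 1]; s <- m[, 2]
  if (!is.null(params$lambda_u)) u <- rpois(n_cells, params$lambda_u * u)
  if (!is.null(params$lambda_s)) s <- rpois(n_cells, params$lambda_s * s)
  list(u = u, s = s)
}

#' Simulate a complete dataset: traits, counts and covariate
#'
#' Composes [simulate_traits()] and [simulate_counts()]: per gene and species,
#' the trait values are exponentiated to `(b, gamma)`, a splicing rate is
#' drawn from the configured log-normal, and `cells_per_species` cells are
#' drawn from the stationary law. The expression covariate is the true
#' cross-species mean of `log b - log gamma` (log mean spliced expression)
#' plus Gaussian noise.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`: `truth` (traits/labels/optima),
#'   `counts` (per-species [paired_counts()]), `log_beta` (genes x species
#'   matrix), `covariate` (named vector), `config`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_traits(config)
  tr <- config$tree
  n <- length(tr$tip.label)
  G <- config$n_genes
  set.seed(config$seed + 1L)
  log_beta <- matrix(rnorm(G * n, config$log_beta_mean, config$log_beta_sd), G, n,
                     dimnames = list(truth$traits$gene_ids, tr$tip.label))
  counts <- vector("list", n)
  names(counts) <- tr$tip.label
  for (si in seq_len(n)) {
    U <- matrix(0L, config$cells_per_species, G)
    S <- matrix(0L, config$cells_per_species, G)
    for (g in seq_len(G)) {
      # per-(gene, species) substream derived from the master seed so
      # generation order cannot matter
      set.seed((config$seed + 104729L * si + 7919L * g) %% .Machine$integer.max)
      p <- kinetic_params(exp(truth$traits$Y[g, 2 * si - 1]),
                          exp(log_beta[g, si]),
                          exp(truth$traits$Y[g, 2 * si]),
                          lambda_u = config$lambda_u, lambda_s = config$lambda_s)
      cs <- simulate_counts(p, config$cells_per_species)
      U[, g] <- cs$u; S[, g] <- cs$s
    }
    counts[[si]] <- paired_counts(tr$tip.label[si], truth$traits$gene_ids, U, S)
  }
  set.seed(config$seed + 2L)
  log_mu <- truth$traits$Y[, seq(1, 2 * n, 2), drop = FALSE] -
            truth$traits$Y[, seq(2, 2 * n, 2), drop = FALSE]
  covariate <- rowMeans(log_mu) + rnorm(G, 0, config$covariate_sd)
  names(covariate) <- truth$traits$gene_ids
  structure(list(truth = truth, counts = counts, log_beta = log_beta,
                 covariate = covariate, config = config),
            class = "sim_dataset")
}

#' Write a simulated dataset in the formats the pipeline reads
#'
#' Newick tree, per-species MTX count pairs, covariate TSV, and truth tables
#' (traits, labels, optima).
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(ds$config$tree, file.path(dir, "tree.nwk"))
  for (sp in names(ds$counts)) {
    write_paired_counts(ds$counts[[sp]], file.path(dir, sp), format = "mtx")
  }
  write.table(data.frame(gene = names(ds$covariate), covariate = ds$covariate),
              file.path(dir, "covariate.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_trait_table(ds$truth$traits, file.path(dir, "true_traits.tsv"))
  write.table(data.frame(gene = ds$truth$traits$gene_ids,
                         label = ds$truth$labels,
                         theta_c = ds$truth$optima[, 1],
                         theta_mu = ds$truth$optima[, 2]),
              file.path(dir, "true_components.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
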