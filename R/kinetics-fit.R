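#' Fit bursty-model kinetics for a single gene
#'
#' Maximum-likelihood estimation of `(log b, log beta, log gamma)` (with the
#' burst initiation rate fixed at `k = 1`) from one gene's paired
#' unspliced/spliced counts, under the stationary CME law with optional
#' Poisson technical noise. Optimization is bounded quasi-Newton (L-BFGS-B) in
#' log space, restarted from a method-of-moments initialization plus random
#' jitter.
#'
#' Genes with fewer than `min_nonzero` nonzero entries in either matrix are
#' flagged unfittable (MLE degenerates at the parameter boundary) and return
#' `converged = FALSE` with `NA` estimates.
#'
#' @param u,s Nonnegative integer count vectors (cells).
#' @param noise `NULL` for noise-free, or `c(lambda_u, lambda_s)` fixed
#'   capture intensities.
#' @param restarts Number of optimizer starts (first is moment-based).
#' @param min_cells Minimum number of cells required.
#' @param min_nonzero Unfittable-gene threshold.
#' @param seed Integer seed controlling the restart jitter (reproducible per
#'   gene).
#' @param quad_tol Quadrature tolerance for the PMF.
#' @return List with `log_b`, `log_beta`, `log_gamma`, `loglik`, `converged`,
#'   `flag` (one of `"ok"`, `"unfittable"`, `"opt_failure"`).
#' @export
fit_gene_kinetics <- function(u, s, noise = NULL, restarts = 5, min_cells = 50,
                              min_nonzero = 5, seed = 1, quad_tol = 1e-9) {
  if (length(u) != length(s)) stop("u and s must have equal length")
  if (length(u) < min_cells) {
    warning(sprintf("only %d cells (< %d); fitting anyway", length(u), min_cells))
  }
  na_fit <- function(flag) list(log_b = NA_real_, log_beta = NA_real_,
                                log_gamma = NA_real_, loglik = NA_real_,
                                converged = FALSE, flag = flag)
  if (sum(u > 0) < min_nonzero || sum(s > 0) < min_nonzero) {
    return(na_fit("unfittable"))
  }
  lam_u <- if (is.null(noise)) NULL else noise[1]
  lam_s <- if (is.null(noise)) NULL else noise[2]

  init <- moment_init(u, s, lam_u, lam_s)
  # collapse identical cells once; likelihood cost is then per unique pair
  tab <- table(u, s)
  uu <- as.integer(rownames(tab)); ss <- as.integer(colnames(tab))
  cnt <- unclass(tab)
  max_u <- max(u); max_s <- max(s)
  negll <- function(th) {
    p <- tryCatch(kinetic_params(exp(th[1]), exp(th[2]), exp(th[3]),
                                 lambda_u = lam_u, lambda_s = lam_s),
                  error = function(e) NULL)
    if (is.null(p)) return(1e12)
    # barrier against parameter corners whose truncation grid would dwarf the
    # data: the MLE's predicted moments cannot exceed the observed range by
    # orders of magnitude
    gr <- default_grid(p, max_u, max_s)
    if (prod(gr) > 2^15) return(1e12)
    # fixed 128-node rule during optimization (well below 1e-9 error for the
    # double-exponential rule); the reported optimum is re-evaluated adaptively
    P <- tryCatch(steady_state_pmf(p, max_u = max_u, max_s = max_s,
                                   quad_tol = quad_tol, n_quad = 128),
                  error = function(e) NULL)
    if (is.null(P)) return(1e12)
    -sum(cnt * log(pmax(P[uu + 1, ss + 1, drop = FALSE], 1e-300)))
  }
  # search box: global [-7, 7] intersected with a window around the moment
  # start
  lower <- pmax(init - 3, -7); upper <- pmin(init + 3, 7)
  init <- pmin(pmax(init, lower), upper)
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  for (r in seq_len(restarts)) {
    th0 <- if (r == 1) init else pmin(pmax(init + rnorm(3, 0, 0.5), lower), upper)
    fit <- tryCatch(
      optim(th0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300, factr = 1e8)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e12) {
    return(na_fit("opt_failure"))
  }
  ll <- tryCatch(
    counts_loglik(u, s, kinetic_params(exp(best$par[1]), exp(best$par[2]),
                                       exp(best$par[3]), lambda_u = lam_u,
                                       lambda_s = lam_s), quad_tol = quad_tol),
    error = function(e) -best$value)
  list(log_b = best$par[1], log_beta = best$par[2], log_gamma = best$par[3],
       loglik = ll, converged = best$convergence == 0, flag = "ok")
}

# Method-of-moments start: E[U] = b/beta with Fano(U) = 1 + b, E[S] = b/gamma
# (noise-free); under Poisson(lambda X) observation, moments are mapped back
# before inversion.
moment_init <- function(u, s, lam_u = NULL, lam_s = NULL) {
  mu_u <- mean(u); va_u <- var(u)
  mu_s <- mean(s)
  if (!is.null(lam_u)) {
    va_u <- max((va_u - lam_u * mu_u) / lam_u^2, 1e-3)
    mu_u <- mu_u / lam_u
  }
  if (!is.null(lam_s)) mu_s <- mu_s / lam_s
  b0 <- max(va_u / max(mu_u, 1e-8) - 1, 0.05)
  beta0 <- max(b0 / max(mu_u, 1e-8), 1e-3)
  gamma0 <- max(b0 / max(mu_s, 1e-8), 1e-3)
  pmin(pmax(log(c(b0, beta0, gamma0)), -7), 7)
}

#' Fit kinetics for every gene of one species
#'
#' Applies [fit_gene_kinetics()] column-wise over a paired count object. In
#' `noise_mode = "grid"` a shared `(lambda_u, lambda_s)` pair is selected for
#' the species by refitting all genes at every grid point and keeping the
#' technical-parameter setting with the best summed likelihood.
#'
#' @param pc A [paired_counts()] object.
#' @param noise_mode `"none"` (default), `"fixed"` or `"grid"`.
#' @param noise For `"fixed"`: `c(lambda_u, lambda_s)`. For `"grid"`: a list
#'   of such pairs.
#' @param seed Master seed; each gene's restart stream is derived from it and
#'   the gene index.
#' @param ... Passed to [fit_gene_kinetics()].
#' @return A data.frame `gene, species, log_b, log_beta, log_gamma, loglik,
#'   converged, flag`; attribute `"noise"` records the selected lambdas.
#' @export
fit_species_kinetics <- function(pc, noise_mode = c("none", "fixed", "grid"),
                                 noise = NULL, seed = 1, ...) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(inherits(pc, "paired_counts"))
  fit_all <- function(lam) {
    rows <- lapply(seq_along(pc$gene_ids), function(g) {
      f <- fit_gene_kinetics(pc$U[, g], pc$S[, g], noise = lam,
                             seed = seed + 7919L * g, ...)
      data.frame(gene = pc$gene_ids[g], species = pc$species_id,
                 log_b = f$log_b, log_beta = f$log_beta,
                 log_gamma = f$log_gamma, loglik = f$loglik,
                 converged = f$converged, flag = f$flag,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  if (noise_mode == "none") {
    out <- fit_all(NULL); attr(out, "noise") <- NULL
  } else if (noise_mode == "fixed") {
    if (is.null(noise)) stop("noise_mode='fixed' requires noise = c(lambda_u, lambda_s)")
    out <- fit_all(noise); attr(out, "noise") <- noise
  } else {
    if (!is.list(noise) || !length(noise)) stop("noise_mode='grid' requires a list of lambda pairs")
    fits <- lapply(noise, fit_all)
    tot <- vapply(fits, function(f) sum(f$loglik, na.rm = TRUE), 0)
    out <- fits[[which.max(tot)]]
    attr(out, "noise") <- noise[[which.max(tot)]]
  }
  out
}

#' Mean-center a kinetics table within each species
#'
#' Subtracts, for every species, the across-gene mean of each log parameter,
#' producing the traits used by the phylogenetic models. Gene-by-gene
#' differences within a species are preserved exactly; the operation is
#' idempotent.
#'
#' @param table Long-format data.frame with columns `gene`, `species` and the
#'   log-parameter columns.
#' @param cols Columns to center.
#' @return The table with centered columns and attribute `"centered" = TRUE`.
#' @export
mean_center <- function(table, cols = c("log_b", "log_beta", "log_gamma")) {
  cols <- intersect(cols, names(table))
  if (!length(cols)) stop("no parameter columns to center")
  if (anyNA(table[cols])) stop("missing cells: complete the ortholog table before centering")
  for (cc in cols) {
    mu <- tapply(table[[cc]], table$species, mean)
    table[[cc]] <- table[[cc]] - as.numeric(mu[as.character(table$species)])
  }
  attr(table, "centered") <- TRUE
  table
}

#' Intersect per-species kinetics tables over successfully fitted orthologs
#'
#' Keeps only genes whose fit converged (and was not flagged) in every
#' species, in stable order of the first table. An optional `gene_map`
#' (data.frame `species, gene, ortholog`) translates species-local gene ids to
#' shared ortholog ids before intersecting.
#'
#' @param tables List of per-species kinetics data.frames
#'   (from [fit_species_kinetics()]).
#' @param gene_map Optional id translation table.
#' @return A single long-format data.frame covering the common gene set.
#' @export
harmonize_orthologs <- function(tables, gene_map = NULL) {
  if (!length(tables)) stop("no tables supplied")
  if (!is.null(gene_map)) {
    tables <- lapply(tables, function(tb) {
      key <- paste(tb$species, tb$gene)
      idx <- match(key, paste(gene_map$species, gene_map$gene))
      if (anyNA(idx)) stop("gene_map does not cover all fitted genes")
      tb$gene <- gene_map$ortholog[idx]
      tb
    })
  }
  ok_sets <- lapply(tables, function(tb) tb$gene[tb$converged & tb$flag == "ok"])
  common <- Reduce(intersect, ok_sets)
  if (!length(common)) stop("empty ortholog intersection: no gene fitted in all species")
  out <- do.call(rbind, lapply(tables, function(tb) tb[match(common, tb$gene), , drop = FALSE]))
  rownames(out) <- NULL
  out
}
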