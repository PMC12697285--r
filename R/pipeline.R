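#' Run the full analysis pipeline
#'
#' counts -> per-gene kinetics -> ortholog harmonization -> per-species
#' mean-centering -> trait table -> mixture fits for the requested model kinds
#' -> AIC comparison. Inputs are either in-memory objects (a `sim_dataset` or
#' a list of [paired_counts()]) or paths on disk; all intermediates can be
#' persisted.
#'
#' @param tree A `phylo` tree, or path to a newick file.
#' @param counts List of [paired_counts()] (one per species, names matching
#'   tip labels), or a directory containing `<species>.unspliced.mtx` etc.
#' @param kinds Model kinds to fit.
#' @param noise_mode,noise Technical-noise handling, see
#'   [fit_species_kinetics()].
#' @param restarts Kinetics optimizer restarts per gene.
#' @param n_starts Mixture optimizer starts.
#' @param fix_prior_means Passed to [fit_mixture()].
#' @param seed Master seed.
#' @param out_dir Optional directory for persisted intermediates.
#' @return List of class `pipeline_result`: `kinetics` (long table),
#'   `traits`, `fits` (per kind), `aic_table`, `seed`.
#' @export
run_pipeline <- function(tree, counts, kinds = c("gamma_constrained",
                                                 "b_constrained", "independent"),
                         noise_mode = "none", noise = NULL, restarts = 2,
                         n_starts = 5, fix_prior_means = FALSE, seed = 1,
                         out_dir = NULL) {
  if (is.character(tree)) tree <- read_tree(tree, file = TRUE)
  if (is.character(counts)) {
    dir <- counts
    counts <- lapply(tree$tip.label, function(sp) {
      pre <- file.path(dir, sp)
      if (!file.exists(paste0(pre, ".unspliced.mtx"))) {
        stop(sprintf("[stage: load_counts] missing counts for species '%s' under %s", sp, dir))
      }
      read_paired_counts(pre, sp)
    })
    names(counts) <- tree$tip.label
  }
  missing_sp <- setdiff(tree$tip.label, names(counts))
  if (length(missing_sp)) {
    stop("[stage: load_counts] no counts for species: ", paste(missing_sp, collapse = ", "))
  }
  tables <- lapply(tree$tip.label, function(sp) {
    tryCatch(fit_species_kinetics(counts[[sp]], noise_mode = noise_mode,
                                  noise = noise, seed = seed, restarts = restarts),
             error = function(e) stop("[stage: fit_kinetics] ", conditionMessage(e)))
  })
  joint <- tryCatch(harmonize_orthologs(tables),
                    error = function(e) stop("[stage: harmonize] ", conditionMessage(e)))
  centered <- mean_center(joint)
  traits <- trait_table(centered, tree$tip.label)
  div <- divergence_structure(tree)
  fits <- lapply(kinds, function(k) {
    tryCatch(fit_mixture(traits, div, k, n_starts = n_starts,
                         fix_prior_means = fix_prior_means, seed = seed),
             error = function(e) stop("[stage: fit_mixture:", k, "] ", conditionMessage(e)))
  })
  names(fits) <- kinds
  aic <- compare_models(fits)
  res <- structure(list(kinetics = centered, traits = traits, fits = fits,
                        aic_table = aic, seed = seed),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(centered, file.path(out_dir, "kinetics_centered.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write_trait_table(traits, file.path(out_dir, "traits.tsv"))
    write.table(aic, file.path(out_dir, "aic_table.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(lapply(fits, fit_to_list),
                         file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

fit_to_list <- function(fit) {
  list(kind = fit$kind,
       alpha_b = fit$spec$alpha_b, alpha_gamma = fit$spec$alpha_gamma,
       sigma_b = fit$spec$sigma_b, sigma_gamma = fit$spec$sigma_gamma,
       p_wn = fit$p_wn,
       m_c = fit$prior$m_c, m_mu = fit$prior$m_mu,
       v_c = fit$prior$v_c, v_mu = fit$prior$v_mu,
       v_wn_b = fit$wn$v_wn_b, v_wn_gamma = fit$wn$v_wn_gamma,
       loglik = fit$loglik, aic = fit$aic, n_params = fit$n_params,
       converged = fit$converged, seed = fit$seed,
       posterior_wn = as.list(fit$posterior_wn))
}

#' Trait-level model-selection simulation study
#'
#' For each generating model kind and replicate: simulate traits from the
#' mixture, fit all three kinds, and record the AIC winner. Summarized as a
#' confusion matrix (rows = generating kind, columns = selected kind).
#'
#' @param gen_specs Named list of [coevo_model_spec()] (one per generating
#'   kind); defaults to the three fitted parameter sets of the study
#'   ([reference_model_specs()]).
#' @param p_wn Named numeric, generating mixture weight per kind.
#' @param n_reps Replicates per generating kind.
#' @param n_genes,tree,prior,wn Generating configuration.
#' @param n_starts,fix_prior_means Fitting configuration.
#' @param seed Master seed.
#' @return List of class `study_report`: `confusion` (matrix), `details`
#'   (per-replicate data.frame), and the configuration.
#' @export
model_selection_study <- function(gen_specs = reference_model_specs(),
                                  p_wn = c(gamma_constrained = 0.149,
                                           b_constrained = 0.900,
                                           independent = 0.329),
                                  n_reps = 20, n_genes = 167,
                                  tree = default_study_tree(),
                                  prior = optima_prior(), wn = white_noise_spec(),
                                  n_starts = 4, fix_prior_means = FALSE,
                                  seed = 1) {
  kinds <- names(gen_specs)
  div <- divergence_structure(tree)
  rows <- list()
  for (gk in kinds) {
    for (r in seq_len(n_reps)) {
      rep_seed <- (seed + 1000L * match(gk, kinds) + r) %% .Machine$integer.max
      cfg <- sim_config(tree = tree, spec = gen_specs[[gk]], prior = prior,
                        wn = wn, p_wn = p_wn[[gk]], n_genes = n_genes,
                        seed = rep_seed)
      sim <- simulate_traits(cfg)
      fits <- lapply(kinds, function(k)
        fit_mixture(sim$traits, div, k, n_starts = n_starts,
                    fix_prior_means = fix_prior_means, seed = rep_seed))
      names(fits) <- kinds
      aics <- vapply(fits, `[[`, 0, "aic")
      win <- kinds[which.min(aics)]
      truefit <- fits[[gk]]
      rows[[length(rows) + 1L]] <- data.frame(
        generating = gk, replicate = r, selected = win,
        aic_gamma = aics[["gamma_constrained"]],
        aic_b = aics[["b_constrained"]],
        aic_indep = aics[["independent"]],
        alpha_b_hat = truefit$spec$alpha_b,
        alpha_gamma_hat = truefit$spec$alpha_gamma,
        sigma_b_hat = truefit$spec$sigma_b,
        sigma_gamma_hat = truefit$spec$sigma_gamma,
        p_wn_hat = truefit$p_wn,
        stringsAsFactors = FALSE)
    }
  }
  details <- do.call(rbind, rows)
  confusion <- table(factor(details$generating, levels = kinds),
                     factor(details$selected, levels = kinds))
  structure(list(confusion = unclass(confusion), details = details,
                 n_reps = n_reps, n_genes = n_genes, seed = seed),
            class = "study_report")
}

#' The study's fitted parameter sets, as generating values for simulations
#'
#' @return Named list of [coevo_model_spec()], one per model kind.
#' @export
reference_model_specs <- function() {
  list(
    gamma_constrained = coevo_model_spec("gamma_constrained", 31.5, 2.33, 0.923, 1.06),
    b_constrained     = coevo_model_spec("b_constrained", 0.022, 3.56, 3.01, 0.169),
    independent       = coevo_model_spec("independent", 1.36, 1.59, 0.651, 0.831)
  )
}

#' Parameter-recovery simulation study
#'
#' Simulates traits under one generating kind and refits the same kind,
#' reporting per-parameter bias and RMSE (on the natural scale for `p_wn`,
#' relative for the positive rates).
#'
#' @param spec Generating [coevo_model_spec()].
#' @param p_wn Generating mixture weight.
#' @param n_reps,n_genes,tree,prior,wn Generating configuration.
#' @param n_starts,fix_prior_means Fitting configuration.
#' @param seed Master seed.
#' @return List of class `study_report` with `estimates` (per replicate) and
#'   `summary` (bias/RMSE/median relative error per parameter).
#' @export
parameter_recovery_study <- function(spec = reference_model_specs()$gamma_constrained,
                                     p_wn = 0.149, n_reps = 10, n_genes = 167,
                                     tree = default_study_tree(),
                                     prior = optima_prior(),
                                     wn = white_noise_spec(),
                                     n_starts = 4, fix_prior_means = FALSE,
                                     seed = 1) {
  div <- divergence_structure(tree)
  est <- lapply(seq_len(n_reps), function(r) {
    rep_seed <- (seed + r) %% .Machine$integer.max
    cfg <- sim_config(tree = tree, spec = spec, prior = prior, wn = wn,
                      p_wn = p_wn, n_genes = n_genes, seed = rep_seed)
    sim <- simulate_traits(cfg)
    fit <- fit_mixture(sim$traits, div, spec$kind, n_starts = n_starts,
                       fix_prior_means = fix_prior_means, seed = rep_seed)
    c(alpha_b = fit$spec$alpha_b, alpha_gamma = fit$spec$alpha_gamma,
      sigma_b = fit$spec$sigma_b, sigma_gamma = fit$spec$sigma_gamma,
      p_wn = fit$p_wn)
  })
  E <- do.call(rbind, est)
  truth <- c(alpha_b = spec$alpha_b, alpha_gamma = spec$alpha_gamma,
             sigma_b = spec$sigma_b, sigma_gamma = spec$sigma_gamma,
             p_wn = p_wn)
  rel_err <- sweep(abs(sweep(E, 2, truth)), 2, truth, "/")
  summary <- data.frame(
    parameter = names(truth), truth = truth,
    median_estimate = apply(E, 2, stats::median),
    bias = colMeans(E) - truth,
    rmse = sqrt(colMeans(sweep(E, 2, truth)^2)),
    median_rel_error = apply(rel_err, 2, stats::median),
    row.names = NULL)
  structure(list(estimates = E, summary = summary, truth = truth,
                 n_reps = n_reps, n_genes = n_genes, seed = seed),
            class = "study_report")
}

#' Render a plain-text report of fits and studies
#'
#' AIC ranking, fitted-parameter table (selection rates, diffusion scales,
#' mixture weight) and, when binned fits are supplied, the per-bin selection
#' rate on the decay coordinate with bin sizes.
#'
#' @param fits Named list of `mixture_fit` (or `NULL`).
#' @param binned Result of [fit_by_bins()] (or `NULL`).
#' @param study A `study_report` (or `NULL`).
#' @param file Optional path; when given the report is also written there.
#' @return The report, invisibly, as a character vector of lines.
#' @export
render_report <- function(fits = NULL, binned = NULL, study = NULL, file = NULL) {
  out <- character()
  push <- function(...) out <<- c(out, sprintf(...))
  if (!is.null(fits) && length(fits)) {
    push("== AIC model comparison ==")
    tb <- compare_models(fits)
    push("%-18s %8s %12s %12s %10s", "model", "k", "logL", "AIC", "dAIC")
    for (i in seq_len(nrow(tb))) {
      push("%-18s %8d %12.2f %12.2f %10.2f", tb$model[i], tb$n_params[i],
           tb$loglik[i], tb$aic[i], tb$delta_aic[i])
    }
    push("")
    push("== Fitted parameters ==")
    push("%-18s %10s %10s %10s %10s %8s", "model", "alpha_b", "alpha_g",
         "sigma_b", "sigma_g", "p_wn")
    for (f in fits) {
      push("%-18s %10.4g %10.4g %10.4g %10.4g %8.3f", f$kind, f$spec$alpha_b,
           f$spec$alpha_gamma, f$spec$sigma_b, f$spec$sigma_gamma, f$p_wn)
    }
    push("")
  }
  if (!is.null(binned)) {
    push("== Expression-binned fits (alpha_gamma per bin) ==")
    push("%-6s %8s %12s %8s", "bin", "n_genes", "alpha_gamma", "p_wn")
    for (k in seq_along(binned$fits)) {
      f <- binned$fits[[k]]
      push("%-6d %8d %12.4g %8.3f", k, binned$sizes[k],
           f$spec$alpha_gamma, f$p_wn)
    }
    push("")
  }
  if (!is.null(study) && !is.null(study$confusion)) {
    push("== Model-selection confusion matrix (rows: generating) ==")
    cn <- colnames(study$confusion)
    push("%-18s %s", "", paste(sprintf("%18s", cn), collapse = ""))
    for (i in seq_len(nrow(study$confusion))) {
      push("%-18s %s", rownames(study$confusion)[i],
           paste(sprintf("%18d", study$confusion[i, ]), collapse = ""))
    }
    push("")
  }
  if (!length(out)) out <- "no results"
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
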