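# phyloburst

Which biophysical lever does evolution pull to change gene expression?
`phyloburst` is an R package for researchers studying gene-expression
evolution with multi-species single-cell RNA-seq. It combines two layers:

1. **Bursty-transcription inference.** Under the bursty model
   `∅ →(k) B×U`, `U →(β) S`, `S →(γ) ∅` (geometric bursts of mean size `b`,
   all rates in units of the burst initiation rate `k`), the stationary joint
   law of unspliced/spliced counts is computed from the chemical master
   equation via its generating function (with optional Poisson technical
   noise), and per-gene maximum-likelihood estimates of
   `(log b, log β, log γ)` are obtained per species. The stationary mean
   spliced abundance is `μ = b/γ`, independent of `β`.

2. **Phylogenetic coevolution models.** The traits `X = (log b, log γ)`
   evolve along a time-calibrated species tree as a bivariate
   Ornstein–Uhlenbeck process `dX = −H(X − X̂)dt + Σ dW`. Three selection
   structures are compared by AIC:
   decay-rate-constrained `H = [[α_b, −α_b], [0, α_γ]]` (selection on decay
   rate and on mean expression; burst size adapts), burst-size-constrained
   `H = [[α_b, 0], [−α_γ, α_γ]]`, and independent `H = diag(α_b, α_γ)`.
   Gene-specific optima are integrated out analytically over a Gaussian
   prior, and a white-noise mixture component (weight `p_wn`) absorbs genes
   without phylogenetic signal.

A synthetic-data module generates trait histories (exact OU transition
sampling on the tree) and count matrices (Gillespie sampling of the bursty
CME), so the entire pipeline is testable end to end by simulation.

## Worked example

Simulate a 167-gene trait table under the decay-rate-constrained model
(generating values `α_b = 31.5`, `α_γ = 2.33`, `σ_b = 0.923`,
`σ_γ = 1.06`, `p_wn = 0.149` on a six-tip tree of unit height), then fit all
three models:

```r
library(phyloburst)
cfg <- sim_config(seed = 3)               # gamma-constrained defaults
sim <- simulate_traits(cfg)
div <- divergence_structure(cfg$tree)

f_g <- fit_mixture(sim$traits, div, "gamma_constrained", n_starts = 4, seed = 3)
f_b <- fit_mixture(sim$traits, div, "b_constrained",     n_starts = 4, seed = 3)
f_i <- fit_mixture(sim$traits, div, "independent",       n_starts = 4, seed = 3)
print(f_g)
#> mixture fit [gamma_constrained]: logL = -946.25, AIC = 1914.51 (k = 11)
#>   alpha_b = 36.27, alpha_gamma = 1.952, sigma_b = 1.022, sigma_gamma = 1.013
#>   p_wn = 0.135
compare_models(list(f_g, f_b, f_i))
#>               model n_params     loglik      aic delta_aic
#> 1 gamma_constrained       11  -946.2538 1914.508    0.0000
#> 2     b_constrained       11 -1007.5842 2037.168  122.6609
#> 3       independent       11 -1656.7976 3335.595 1421.0877
```

The generating model wins by >120 AIC units, and the selection rates,
diffusion scales and white-noise weight land close to the generating values
— the package's simulation studies (`model_selection_study()`,
`parameter_recovery_study()`) quantify this across replicates.

For count-level data, `run_pipeline()` chains per-gene kinetics fitting,
ortholog harmonization, per-species mean-centering and the model comparison;
`fit_by_bins()` refits within expression terciles (167 genes split
56/55/56); `simulate_dataset()` + `write_sim_dataset()` produce
newick/Matrix-Market/TSV inputs in the formats the pipeline reads. A thin
command-line wrapper lives at `inst/cli/phyloburst-cli.R`.

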