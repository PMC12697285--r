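---
title: "Modeling the coevolution of transcriptional burst size and mRNA decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the coevolution of transcriptional burst size and mRNA decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Steady-state mRNA abundance is a composite phenotype: in the bursty
transcription model it equals the ratio of transcriptional burst size to mRNA
decay rate. When stabilizing selection acts only on mean expression, the
underlying biophysical parameters are free to wander in compensating
directions (systems drift). `phyloburst` implements a two-layer analysis that
asks *which* biophysical lever is constrained across species:

1. a **biophysical layer** that estimates per-gene burst size `b`, splicing
   rate `beta` and decay rate `gamma` from spliced/unspliced single-cell
   count matrices, per species, under a chemical master equation (CME); and
2. a **phylogenetic layer** that models the evolution of `(log b, log gamma)`
   along a time-calibrated species tree as a bivariate Ornstein-Uhlenbeck
   (OU) process, in three competing variants, compared by AIC.

## The biophysical model

Transcriptional bursts arrive as a Poisson process with rate `k`; each burst
deposits a geometric number of unspliced molecules (support `0, 1, ...`,
mean `b`); unspliced molecules are spliced at per-molecule rate `beta`, and
spliced molecules decay at rate `gamma`. Only rates *relative to* `k` are
identifiable from a single stationary snapshot, so all rates are expressed in
units of `k` (`k = 1`). The stationary mean spliced abundance is
`mu = b / gamma`, independent of `beta` — which is why the phylogenetic layer
tracks `(log b, log gamma)` and treats `log mu = log b - log gamma` as the
expression phenotype.

The stationary joint law of (unspliced, spliced) counts is evaluated through
its probability generating function,

```
log G(x_u, x_s) = k * Int_0^Inf  b f(s) / (1 - b f(s)) ds,
f(s) = g_u e^{-beta s} + g_s * beta (e^{-gamma s} - e^{-beta s}) / (beta - gamma),
```

with `g = x - 1`. Poisson technical noise with capture intensity `lambda`
per molecule enters by composing with the Poisson observation kernel,
`g = exp(lambda (x - 1)) - 1`. The generating function is evaluated on a 2-D
roots-of-unity grid and inverted by FFT.

Numerical choices:

* **Quadrature.** The integrand has algebraic behavior in `e^{-s}` at both
  endpoints whose exponents (`beta/gamma` ratios) are generally fractional,
  which defeats fixed polynomial rules. We therefore use double-exponential
  (exp-sinh) quadrature, under which the trapezoid rule converges
  geometrically; the node count is doubled adaptively until the log
  generating function is stable to `1e-10` (roughly 100-200 nodes in
  practice). The `beta == gamma` case uses the analytic limit
  `beta * s * e^{-beta s}`, not an epsilon perturbation.
* **Truncation.** The grid covers `mean + 15 sd` of each marginal (negative
  binomial for U; Fano-factor bound for S), floor 16, rounded up to powers of
  two for the FFT, and doubled whenever retained mass falls below `1 - 1e-6`
  or observed counts fall outside — data can therefore never silently hit a
  `-Inf` likelihood.
* **Likelihood and optimizer.** Identical `(u, s)` cells are collapsed before
  evaluation, so likelihood cost does not grow with cell number. The MLE runs
  bounded quasi-Newton (L-BFGS-B) on `(log b, log beta, log gamma)` in
  `[-7, 7]^3` intersected with a window of width 6 around a method-of-moments
  start (`Fano(U) = 1 + b`, `E[U] = b/beta`, `E[S] = b/gamma`), with
  restarts jittered by `N(0, 0.5^2)`; the window plus a truncation-size
  barrier keeps the optimizer out of parameter corners whose grid would
  dwarf the data. Genes with fewer than 5 nonzero counts in either matrix
  are flagged unfittable (the MLE degenerates at the boundary).
* **Technical noise.** Default is noise-free. A grid mode refits all genes of
  a species at each candidate `(lambda_u, lambda_s)` pair and keeps the pair
  with the best summed likelihood, sharing one setting per species.

## The phylogenetic model

Let `X_t = (log b_t, log gamma_t)`. Evolution along each branch follows

```
dX_t = -H (X_t - Xhat) dt + Sigma dW_t,    Sigma = diag(sigma_b, sigma_gamma).
```

The three selection-matrix structures encode the competing hypotheses:

* decay-rate-constrained: `H = [[alpha_b, -alpha_b], [0, alpha_gamma]]` —
  selection acts on `log gamma` and on `log mu`; burst size adapts;
* burst-size-constrained: `H = [[alpha_b, 0], [-alpha_gamma, alpha_gamma]]`;
* independent: `H = diag(alpha_b, alpha_gamma)`.

These drift structures arise from Gaussian fitness functions in the
constrained coordinate and in log mean expression; the package parameterizes
directly by the selection rates `alpha` (per unit branch length) rather than
by fitness curvatures, whose proportionality constants would add nothing
identifiable at this level.

The stationary covariance `Vinf` solves the Lyapunov equation
`H Vinf + Vinf H' = Sigma Sigma'` (reduced to a 3x3 linear system). For tips
`i, j` with MRCA at divergence time `d` before the present, the
stationary-root covariance is `e^{-H d} Vinf e^{-H' d}`. All 2x2 matrix
exponentials use the exact trace/determinant closed form, which is uniformly
valid at `alpha_b == alpha_gamma` and evaluated in `exp(m +/- q)` form to
avoid `cosh` overflow on long branches with strong selection.

**Root convention.** The root state is drawn from the stationary law centered
at the gene's optimum (default). This is the natural companion of
marginalizing gene-specific optima: the optimum shifts all tips jointly and
the stationary law describes the residual variation. A `root = "fixed"`
option instead pins the root at the optimum and uses the non-stationary
transition covariance; it is provided for sensitivity analysis.

**Hierarchical optima and the mixture.** Evolutionary rates are shared across
genes; gene optima `theta = (theta_c, theta_mu)` are Gaussian with estimated
means and variances and are integrated out analytically, contributing the
rank-2 term `A diag(v_c, v_mu) A'` to the tip covariance, where `A` maps
optima to stationary tip means (per-species blocks `[[1,1],[1,0]]`,
`[[1,0],[1,-1]]`, identity for the three kinds). Genes without phylogenetic
signal are absorbed by a white-noise component (probability `p_wn`):
species-iid residuals `diag(v_wn_b, v_wn_gamma)` around the same optima-prior
mean structure. The optima priors are independent across the two coordinates;
the white-noise component keeps gene-level mean heterogeneity because a gene
can lack tree signal while still having its own expression level. Traits are
stacked species-major interleaved, `(b_1, gamma_1, b_2, gamma_2, ...)`,
everywhere.

**Fitting.** The mixture likelihood is maximized by multi-start L-BFGS-B over
11 parameters (log transforms on positive parameters; logit on `p_wn`,
clipped to `[1e-6, 1 - 1e-6]` during optimization and reported unclipped with
a flag when boundary-converged; `fix_prior_means = TRUE` pins the prior means
to zero — natural after per-species centering — and drops two parameters).
One start is moment-based (cross-species variances set the scales), the rest
are random log-uniform draws; `fit_mixture()` defaults to 10 starts. Each
objective evaluation reuses a single Cholesky factorization of each component
covariance across all genes. Models are compared by `AIC = 2k - 2 logL`
(AICc is available behind a flag in `compare_models` consumers via the
returned `n_params` and `loglik`).

## What the generator emulates

`simulate_traits()` draws per-gene components and optima, then recurses down
the tree with *exact* OU transition sampling (no discretization error);
`simulate_counts()` draws stationary cells by independent Gillespie
trajectories, one per cell, burned in for `20 / min(beta, gamma)` time units
from the empty state (validated against doubling the burn-in); the two code
paths — generating function + FFT versus Gillespie — are fully independent,
which is what makes their total-variation agreement informative.
`simulate_dataset()` composes the two: traits are exponentiated to
`(b, gamma)`, `beta` is drawn iid log-normal (mean 0, sd 0.5 on the log
scale) per gene and species — it must exist for the count simulator but
carries no evolutionary signal, so fitted `beta` values should not be
interpreted phylogenetically — and the expression covariate is the true
cross-species mean of `log b - log gamma` plus Gaussian noise (sd 0.3,
emulating a cross-dataset expression estimate such as bulk medians from a
different cohort).

Defaults represent the study conditions: 167 genes, six species, selection
and diffusion rates from the study's decay-rate-constrained fit
(`alpha_b = 31.5`, `alpha_gamma = 2.33`, `sigma_b = 0.923`,
`sigma_gamma = 1.06`, `p_wn = 0.149`). Because those rates are only
meaningful relative to tree height, the default six-tip tree is ultrametric
with height 1 and a mix of shallow and deep splits, standing in for a
time-calibrated vertebrate phylogeny rescaled to unit height; `read_tree()`
accepts any ultrametric newick tree (branch lengths are used as-is, so
`alpha` and `sigma^2` are per branch-length unit). Values the study does not
pin down were fixed once at field-plausible scales: optima-prior variances
`v_c = v_mu = 0.3` and white-noise variances `0.3` per trait — comparable to
the stationary OU variance, so the mixture components overlap realistically
rather than being trivially separable.

What the generator does *not* emulate: library-size variation, batch
effects, cell-type mixtures, doublets, ambient RNA, or mutational
correlation between the two traits. Passing simulation-based tests therefore
validates the estimators under the model's own assumptions, not robustness
to those artifacts in real data.

## Problem sizes used in the validation suite

Simulation studies in the tests and the acceptance script use: 50 genes x
{300, 3000, 30000} cells for kinetics recovery; 2e4 trait histories for
covariance cross-validation; 20 replicates per generating kind (167 genes,
6 tips, 3 optimizer starts) for model selection; Monte-Carlo prior
integration with 4e5 draws. These sizes give Monte-Carlo noise comfortably
below the tolerances they are tested against while keeping a full run on a
single core in the tens of minutes.

One caveat discovered while validating the Gillespie/PMF agreement: the
total-variation distance between a 1e5-sample histogram and its own
generating law has expectation about 0.0116 at `(b = 2, beta = 1.5,
gamma = 0.8)` — sampling noise alone, as confirmed by the analytic
`sum sqrt(2p(1-p)/(pi n))/2` floor and by the U-marginal matching its closed
form to 2.5e-3 at 4e5 samples. Histogram-vs-truth TV checks at that sample
size should therefore be read against this floor rather than against zero.

## Known limitations

* Only two coupled traits; no mutational (Sigma) cross-correlation; no
  per-gene selection or diffusion rates.
* Non-ultrametric trees are rejected (no measurement-error-in-tips
  correction is attempted).
* The technical-noise grid shares one `(lambda_u, lambda_s)` per species;
  per-gene technical parameters are out of scope.
* The white-noise component's variance sharing (one variance per trait,
  shared across genes and species) is one of several defensible outlier
  parameterizations.
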