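---
title: "Models and methods: macroevolution of venom expression composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: macroevolution of venom expression composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phylovenom asks a quantitative-genetics question at macroevolutionary scale:
when a complex trait is a *composition* of gene-expression levels — here, the
percent contribution of each toxin family to a snake's venom transcriptome —
how much of its evolution is channelled by covariance among components
(constraint), and how much of the observed similarity between distantly
related species reflects convergence toward shared adaptive optima? The
package implements the full chain of analyses: a Bayesian multivariate
phylogenetic mixed model for the phylogenetic covariance (PCOV) matrix and
per-component signal, eigen-analysis of the PCOV (the phylomorphospace), a
stepwise Ornstein–Uhlenbeck regime search with a simulated null, and
maximum-likelihood ancestral state reconstruction. This vignette records the
models, the parameter choices, and the reasoning behind the places where the
design was genuinely open.

## The phylogenetic mixed model

The core model is the animal model of quantitative genetics with the
phylogeny substituted for a pedigree. For $n$ species and $m$ components,
responses $y_{ij}$ (component $j$ in species $i$) follow

$$ y = X\beta + u + e, \qquad
   u \sim \mathcal N(0,\, G \otimes A), \qquad
   e \sim \mathcal N(0,\, R \otimes I_n), $$

where $A$ is the species relatedness matrix (shared root-to-MRCA path
lengths), $G$ is the $m \times m$ phylogenetic covariance between components
— the PCOV, the macroevolutionary analogue of the quantitative-genetic
$G$ matrix — and $R$ the residual covariance. Fixed effects are a
per-component intercept and, when the data carry them, per-component
sequencing-technology contrasts: a covariate unrelated to the phylogeny
should not (and, in the model, does not) alter the phylogenetic covariance
estimate, which the test suite checks as a property.

Choices that matter:

* **A-matrix scaling.** `phylo_vcv()` divides the shared-path matrix by the
  tree height, giving unit diagonal on an ultrametric tree. $G$ and $R$ are
  then on the same scale and the per-component signal
  $\lambda_j = G_{jj} / (G_{jj} + R_{jj})$ lives on $[0, 1]$, matching the
  interpretation of Pagel's lambda as phylogenetic heritability. The
  unscaled matrix is available (`scale_height = FALSE`).
* **Response scaling.** Each retained component is centred and scaled to
  unit variance across species before fitting (`response_scaling`, on by
  default), so covariance entries and $\lambda$ are comparable across
  components of very different typical abundance.
* **Priors.** Inverse-Wishart on both $G$ and $R$ with scale $I$ and
  $\nu = m + 1$ — proper and weakly informative. With ~50 species this prior
  contributes the equivalent of one identity-scatter observation block; it
  regularises both covariances symmetrically and biases $\lambda$ mildly
  toward $1/2$ (on simulations with true $\lambda = 0.8$ the posterior mean
  is ≈ 0.70). A near-improper alternative ($\nu = m + 0.002$) is exposed via
  `prior_nu` for sensitivity checks.
* **Sampler.** Blocked Gibbs in compiled code: $\beta$ is drawn from its
  full conditional with $u$ integrated out (working in the eigenbasis of
  $A$, where rows are independent with covariance $d_i G + R$), then
  $u \mid \beta$, then conjugate inverse-Wishart updates. This is an exact
  scheme — no tuning, no Metropolis step — and every stored draw of $G$ and
  $R$ is symmetric positive definite by construction. A generalized
  eigendecomposition of $(G, R)$ reduces all per-species work to $O(m^2)$.
* **Chain lengths.** The default configuration (50,000 iterations, 10,000
  burn-in, thinning 20; about 5 s at $n = 50$, $m = 10$) is the package's
  working scale for tests and examples; `preset = "paper"` records the
  study-scale run (20 million iterations, 1 million burn-in, thinning
  1,500). Effective sample sizes use the initial-positive-sequence rule on
  paired autocorrelations; HPD intervals are shortest empirical intervals.
* **Significance conventions.** An off-diagonal PCOV entry is flagged when
  its 95% HPD excludes zero; no multiple-testing correction is applied (none
  is applied in the analysis this package reproduces, and the flags are
  descriptive). Because $\lambda > 0$ by construction, "signal present" is
  operationalised as HPD lower bound > 0.05.
* **Model comparison.** The clr-validation refit is compared by DIC
  ($2\,\overline{D} - D(\bar\theta)$), with the deviance of the
  $u$-integrated likelihood.

## Compositional considerations

Percent compositions carry a sum constraint that can induce spurious
negative covariance. The pipeline therefore (i) analyses the closed
composition of retained components on the raw percent scale, and (ii)
refits after a centred-log-ratio transform as a robustness check, comparing
the significance masks of the two fits. Structural zeros — genuine absences
of a toxin family — cannot enter a log-ratio, so they are first imputed by
simple multiplicative replacement: every zero becomes
$\delta = 0.65 \times$ (smallest nonzero value in the table) and the nonzero
entries of the row shrink by $1 - k\delta/100$, preserving closure exactly.
The replacement is deterministic, which keeps the validation refit
reproducible; a Bayesian-multiplicative routine would add simulation noise
without changing the check's purpose. Prevalence filtering retains a
component when it is present (> 1e-6%) in at least 50% of species
(inclusive boundary), and rows are re-closed to 100 afterwards so the
retained families form a proper composition.

## Phylomorphospace

PCA is performed on the posterior-mean PCOV itself — not on the raw data
covariance — so the axes are directions of *heritable* covariation; species
scores are projections of the scaled data onto those eigenvectors. Scores
are centred on the arithmetic cross-species mean (a phylogenetically
weighted mean can be supplied via `weights`; nothing downstream is
sensitive to this choice on the synthetic data). Axis signs follow a fixed
convention (largest-magnitude loading positive) so runs are comparable.

## The convergence search

The Hansen model gives each branch an adaptive regime with optimum
$\theta_r$; a trait's tip distribution is Gaussian with OU covariance
$V_{ij} = \tfrac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
(1 - e^{-2\alpha s_{ij}})$ and mean $W\theta$, where $W$ holds
exponentially discounted regime exposures along each root-to-tip path (the
root state is absorbed into the basal regime's column). $\alpha$ and
$\sigma^2$ are shared across regimes within a trait; $\alpha$ is optimised
on the log scale by bounded scalar search with $\theta$ (GLS) and
$\sigma^2$ (ML) profiled out; below $\alpha T < 10^{-8}$ the Brownian limit
$\sigma^2 s_{ij}$ is used directly. The parameter count is
$m(2 + k')$ and model score is AICc with $n = $ species × traits.

The search has a forward phase (add the best regime shift among all
branches, repeat) and a backward phase (merge the best pair of regimes,
repeat). Shift locations are structural: a merge can make a shift's regime
equal its parent's (a reversion), and such shifts still count in $k$.
Convergence is summarised by $k$ (placements incl. basal), $k'$ (distinct
regimes), $\Delta k = k - k'$, and $c$ (placements in regimes reached at
least twice — the basal placement included, so reversions to the basal
regime are convergent with it; this edge-case convention is the package's,
as the quantity is undefined in the underlying description).

**Acceptance thresholds.** The two phases guard different errors, and a
single threshold cannot serve both. Each forward step selects the best of
roughly $2n$ candidate branches, so the best candidate improves the
deviance by about $2\ln(2n)$ (~9 units at 50 tips) by chance alone — more
than the AICc penalty (~4.4) for one extra regime. With a threshold of 0
the forward phase therefore accepts a long tail of spurious singleton
regimes near-deterministically, and their subsequent merging manufactures
convergence on data that contain none (measured: mean $\Delta k \approx 4$
on no-convergence simulations). The forward default is therefore a
10-unit improvement — the multiplicity allowance rounded up — while the
backward default stays at 0, since only $k' (k'-1)/2 \ll 2n$ merges
compete. At these defaults, simulations with three shifts toward one shared
optimum (8 stationary SDs away, $\alpha T = 5$, two traits, 50 tips) are
detected with $c \ge 2$ in 95% of runs, while matched no-convergence
simulations give mean $\Delta k = 0.05$ and recover $k \approx 4$
correctly. Both thresholds are arguments; setting the forward threshold to
0 reproduces the unguarded stepwise rule.

**Scan mode.** Scoring every candidate with a full $\alpha$ re-optimisation
is wasteful: candidates are compared at the current model's per-trait
$\hat\alpha$, and only the selected placement is re-optimised — the
accept/reject decision always uses the fully re-optimised AICc
(`scan = "full"` restores per-candidate optimisation; ~15× slower, same
results on all test scenarios).

**The null.** Following the original procedure, the null model keeps the
final shift locations but gives every shift its own regime, refits, and
simulates traits from that no-convergence Hansen model; the full search is
rerun per iteration and $c$ and $\Delta k$ recorded. P-values use the
add-one convention, $(\#\{c_{null} \ge c_{obs}\} + 1)/(n_{sim} + 1)$,
reported to three decimals. The desk default is 50 simulations (the
study-scale run uses 500; `pipeline_config(preset = "paper")`).

## Ancestral states

Each component is reconstructed independently under Brownian motion by the
contrasts (re-rooting) algorithm, which equals the joint GLS reconstruction
$\hat x_{anc} = C_{at} C_{tt}^{-1} (x - \hat\mu 1) + \hat\mu$ with the GLS
root mean — an equivalence the test suite asserts at $10^{-8}$ against a
dense-matrix oracle. The Brownian rate is the REML contrasts estimate
(mean squared standardised contrast). On topologies where the re-rooting
implementation fails (e.g. star trees) the dense GLS path with kriging
variances is used; the two agree to machine precision where both run.
Confidence intervals are $\pm 1.96\sqrt{\mathrm{var}}$ (95%, matching the
package's other intervals; the level is a package choice). Reconstructed
abundances may be negative — the Gaussian model permits it — and the
root-presence rule handles interpretation: a family is called present at
the root only when the root CI lower bound is strictly positive.

## The synthetic-data generator

The generator produces datasets with the statistical structure the analyses
assume, at the scale of the study they mirror: 52 species on a pure-birth
tree rescaled to 60 My; 10 core toxin families whose latent (log-scale)
abundances evolve as correlated Brownian motion plus residual noise with
$\lambda = 0.8$ for the four strong-signal families and $0.5$ for the rest
(diagonal $G$ and $R$, total latent variance 2, latent means spanning ~3
log units so four families dominate); 15 decoy families present in 20% of
species; structural zeros where a latent value falls more than 6 natural-log
units (≈ 0.25% abundance) below the row maximum — a detection-limit rule;
softmax closure to percent; and technology batch labels drawn independently
of the phylogeny with additive latent shifts (SD 0.3). A softmax of latent
Gaussians was chosen over truncation because it guarantees closure exactly
and controls zero placement explicitly.

What the generator does *not* emulate: within-species venom variation,
non-Gaussian heavy tails in expression noise, correlated batch and clade
membership (real studies sequence related species on similar platforms),
and uncertainty in the input phylogeny. Passing tests on this generator
therefore demonstrates correctness of the machinery and recoverability
under the model's own assumptions, not robustness to their violation.

## Numerical conventions and problem sizes

Ultrametricity is required within $10^{-6} \times$ height (pruned published
trees can deviate slightly from exact ultrametry). Ties in the stepwise
search break by preorder branch index. The OU likelihood floors
$\hat\sigma^2$ at $10^{-12}$ for degenerate (constant) traits; $\alpha T$
is searched in $[10^{-3}, 50]$. All stochastic stages derive their seeds
deterministically from one master seed, so a pipeline report fully
determines a rerun.

The shipped test and example scale — 50-tip trees, 50k-iteration chains,
50 null simulations, 5–20 replicate recovery runs — keeps a full suite run
in a couple of minutes while leaving every estimator well inside its
asymptotic operating range; study-scale presets are one argument away.

## Known limitations

* The PCOV prior biases $\lambda$ toward 0.5 at $n \approx 50$; per-seed
  posterior-mean covariance matrices carry substantial sampling spread
  (relative Frobenius error ~0.6 for $m = 10$), which is a property of the
  data size, not of the sampler — recovery tests average over replicate
  datasets.
* The stepwise search is greedy: it cannot undo a forward placement, and
  the reported $k$ depends on the forward threshold. The null comparison is
  the inferential guard for the convergence metrics, not the raw counts.
* ASR assumes Brownian motion per component on the percent scale;
  reconstructions near the root have wide CIs and negative values are
  possible.
* Every stage assumes the tree is known without error.
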