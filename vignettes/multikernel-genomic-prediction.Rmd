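---
title: "Multi-kernel Bayesian genomic prediction with transcriptome and environment kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel Bayesian genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

omicblup fits genomic-prediction models in which every source of variation —
additive genetics, epistasis, dominance, transcript abundance, and
genotype-by-environment (G×E) interaction — enters as a kernel: a symmetric
positive semi-definite line-by-line (or observation-by-observation)
covariance structure with its own variance component. This vignette explains
the model, the sampler, the synthetic-data generator, and the design
decisions that were genuinely open.

## The model

For a vector of trait observations $y$ over $n$ records (line × environment
× replicate), the general model is

$$ y = \mu + \sum_k u_k + \varepsilon, \qquad
   u_k \sim N(0, \sigma_k^2 K_k), \qquad
   \varepsilon \sim N(0, \sigma_\varepsilon^2 I), $$

with a separate intercept per environment whenever the phenotype table
declares more than one environment, and a single intercept otherwise. The
kernels on offer are:

* **G** — the additive genomic relationship matrix (GRM),
  $G = WW^\top / (2\sum_k p_k(1-p_k))$, where $W$ centres the 0/1/2 marker
  codes by twice the allele frequency. This scaling puts the mean diagonal
  at $1+f$, $f$ the panel's inbreeding coefficient.
* **G#G (EPI)** — the epistatic relationship matrix, the Hadamard square of
  the GRM (PSD by the Schur product theorem).
* **A** — dominance, from the per-marker homozygosity indicator (1 for
  homozygotes, 0 for heterozygotes), column-centred, cross-multiplied and
  rescaled to mean diagonal 1. A fully inbred panel has a constant indicator,
  so the term is inestimable and is dropped with a warning.
* **T** — the transcriptome linear kernel over per-gene standardised
  abundances, rescaled to mean diagonal 1. When abundances are available
  per environment, T is built at observation level, so it carries
  environment-specific expression signal — the route by which an
  endophenotype measured under each treatment captures G×E.
* **G\*** (RKHS) — a Gaussian kernel $\exp(-d^2_{ij}/h)$ over marker
  profiles, absorbing additive plus cryptic non-additive effects in a single
  term; this is why the RKHS scenarios never carry separate EPI/A terms.
* **G×E** — the multi-environment single-variance block kernel
  $(Z_g G Z_g^\top) \circ (Z_E Z_E^\top)$: within-environment blocks equal
  the observation-expanded G (or G\*), cross-environment blocks are zero.

Thirteen published model scenarios combine these terms
(`scenario_ids()`), from the GBLUP benchmark `G` up to
`G_T_GE_EPI_A` and the RKHS variants.

## Inference

All variances carry scaled inverse-$\chi^2$ priors; the intercepts are flat.
Every full conditional is conjugate, so the model is fitted by a Gibbs
sampler. Each kernel is eigen-decomposed once, $K = U\Lambda U^\top$, and
the sampler works on the transformed coordinates $s = U^\top u$ with prior
$N(0, \Lambda\sigma^2_u)$ and working response $U^\top y$: every effect
update is then a set of independent scalar Gaussian draws, which is what
makes chains over many kernels cheap. Eigenvalues below
$10^{-10}\lambda_{max}$ are truncated (the sampler works in the kernel's
numerical rank), and sampled variances are floored at $10^{-10}$ to avoid
degenerate $\chi^2$ draws. An untransformed sampler
(`method = "direct"`) that draws each $u_k$ from its multivariate-normal
full conditional is retained purely as a cross-check; the test suite
verifies that both samplers agree on posterior means within Monte-Carlo
error.

**Hyperpriors.** Degrees of freedom default to 5 for every variance (the
BGLR convention), with the scale set so each prior mode equals an equal
share of the phenotypic variance split among the terms plus residual,
normalised by the kernel's mean diagonal. Realised values are stored on the
fitted object (`fit$hyperpriors`).

**Chain defaults.** 12,000 iterations, 2,000 burn-in, thinning 5.
Convergence is monitored by an autocorrelation-based effective sample size
on each variance component, with a warning below 100. Cross-validation
fits use much shorter chains (the defaults in `crossvalidate()` are
3,000/1,000/2, and the shipped analyses use 400–1,500 iterations depending
on problem size): accuracy is computed from posterior-mean predictions,
which stabilise far faster than the variance posteriors, and the reported
problem sizes below were chosen so the full scenario catalog remains an
interactive desk-scale computation.

**Missing responses and prediction.** `NA` responses are imputed by data
augmentation each sweep. This is exactly the whole-kernel conditioning used
for cross-validation: kernels are built once on all lines, test phenotypes
are masked, and predictions for masked records are posterior means of the
linear predictor. The bandwidth $h$ of the Gaussian kernel defaults to the
median of the nonzero pairwise squared distances (logged on the kernel and
in the run manifest); whether distances are additionally divided by the
feature count is exposed as `scale_features` rather than guessed.

**GEBVs.** Genomic estimated breeding values are per-line posterior means
of the *genetic* terms only (G, G#G, A, or the RKHS G\*); transcriptome and
G×E terms are bookkept separately, matching the definition of a breeding
value as the summed genetic effects.

## Evaluation protocol

Fivefold cross-validation partitions **lines** (never single observations)
into near-equal folds, so a genotype is never in training and test at once —
with a relationship matrix in the model, observation-level folding would
leak the test genotype wholesale. Accuracy is the Pearson correlation
between observed and predicted phenotypes of held-out lines, computed
within each environment and averaged across environments (stratified
scoring); a pooled correlation is kept for diagnostics, and the two agree
when environments are exchangeable. The reported mean and standard
deviation are taken across the five fold-level accuracies. Repeated trait
measurements (e.g. height scored three times) are analysed as independent
runs whose mean is reported (`replicate_analyses`).

## The synthetic-data generator

The generator emulates the data the analysis expects: an inbred diversity
panel (default 286 lines, 33,174 SNPs, 44,054 transcripts, two contrasting
environments), with these deliberate choices:

* **Genotypes.** Allele frequencies uniform on `maf_range` (default
  0.05–0.5); heterozygote frequency $2p(1-p)(1-f)$ with the inbreeding
  excess on the homozygote classes (default $f = 0.9$: highly selfing
  material with residual heterozygosity, so dominance remains estimable).
  Lines belong to founder families (default 25 families, allele-copy
  probability 0.9). A diversity panel is a mixture of related material, and
  this relatedness is what genomic prediction *is*: with fully independent
  lines the GRM is near-diagonal and no model can predict a held-out line.
  The copy mechanism leaves the marginal per-marker genotype distribution
  untouched, so allele-frequency, heterozygosity and GRM-scaling behaviour
  are unchanged. No linkage map or explicit pedigree is simulated.
* **Transcriptome.** Per-gene abundances on a continuous, already-normalised
  scale (no count layer): a genetic score over a random subset of markers
  (share `transcriptome_h2`, default 0.4), an environment main shift and an
  environment-specific genetic interaction score (together
  `transcriptome_env_frac`, default 0.3, split equally), plus Gaussian
  noise. Abundances are generated per environment.
* **Phenotypes.** Random-effect vectors are drawn from
  (variance × kernel) multivariate Gaussians and expanded to observations
  through incidence matrices; intercepts default to trait-plausible values
  (around 100 days / 90 cm scale with a +5 environment offset) and ground
  truth (effects, noise, variances) is recorded for recovery tests.
* **Two traits.** `trait_additive` is mostly additive
  ($\sigma^2_g = 1$, no G×E; height-like) and `trait_gxe` strongly
  environment-interactive ($\sigma^2_g = 0.15$, $\sigma^2_{ep} = 0.05$,
  $\sigma^2_{gE} = 3$, $\sigma^2_\varepsilon = 0.4$; flowering-like).
* **G×E structure.** The default G×E effect is a reaction norm: a
  genotype-specific sensitivity drawn from the genomic kernel, multiplied
  by a centred environment contrast. Under contrasting treatments
  (photoperiods, sites) lines reorder between environments while their
  across-environment mean carries no interaction signal — which is what
  lets an additive-only model fail on such a trait the way the real data
  show. `gxe_structure = "independent"` gives exchangeable per-environment
  draws instead (and is what the variance-recovery analyses use, being the
  literal multi-environment single-variance data-generating process).
  `gxe_relatedness_share` can blend in a line-idiosyncratic component for
  G×E that genome-wide relatedness does not capture.

Seed discipline: stage $k$ of the generator seeds the base RNG at
`seed + k` (genotypes +0, transcriptome +1, phenotypes +2/+3), so each
stage is individually reproducible and two runs with the same config are
bitwise identical.

**What passing tests do and do not show.** The generator produces
family-structured, linkage-free, equilibrium genotypes and linear
transcript-abundance mediation. Real panels add LD, selection, shared
environments of relatives, non-Gaussian traits and count-scale expression
noise; accuracy figures obtained on synthetic panels characterise the
correctness and relative ordering of the estimators, not the absolute
accuracy to expect on real material.

## Desk-scale analyses shipped with the package

The analyses reproduced by `scripts/acceptance.R` and the test suite use
generator sizes chosen once for interactive runtimes: 500 lines × 2,000
markers for GRM scaling; 50 and 30 lines for the closed-form and
sampler-equivalence checks; 200 lines × 2 environments × 10 replicate
simulations for variance recovery; 150 lines × 1,000 markers × 500 genes
for the scenario-catalog contrasts; 80 lines × 400 markers × 200 genes for
null calibration. At these sizes the qualitative findings are stable across
seeds: modelling G×E lifts accuracy on the interactive trait from ~0.2 to
~0.86; the transcriptome alone reaches ~0.6–0.7; adding T on top of
G + G×E + G#G changes accuracy by less than a fold-level standard error;
and the additive trait is predicted at ~0.77 by the GBLUP benchmark.

## Numerical choices and edge cases

* Kernel symmetry is enforced to $10^{-8}$ relative tolerance; eigenvalues
  above $-10^{-8}\lambda_{max}$ are treated as float noise (typical after
  large Hadamard products) and clipped with a warning, anything lower is an
  error.
* Monomorphic markers are dropped (with a warning) before centring;
  missing genotype codes are mean-imputed per marker ($2p_k$); zero-variance
  genes are dropped before the T kernel.
* Marker codes in `{-1,0,1}` are auto-shifted; value sets compatible with
  both dialects (e.g. only 0/1 observed) are rejected rather than guessed.
* Correlation is reported as `NA` (with a machine-readable warning) for
  cells with fewer than three pairs or zero variance; such cells are
  excluded from the stratified mean.
* Fold assignment uses `rep(1:k)` over a seeded shuffle, so fold sizes
  differ by at most one (286 lines → 58+57+57+57+57).

## Known limitations

Single-trait models only; no marker-effect (BayesA/B/Cπ) parameterisations;
no CV1/CV2 multi-environment validation designs; the RKHS bandwidth is
fixed per fit (median heuristic or user-set), not sampled; variance
components of weakly identified terms (e.g. EPI next to G) mix slowly in
short chains — their posteriors are honest but wide, and the effective
sample size warning exists for this reason.
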