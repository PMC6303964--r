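---
title: "Orthogonal partitioning of genomic variance with epiblup"
author: "epiblup authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal partitioning of genomic variance with epiblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiblup)
```

## The model

`epiblup` estimates additive, dominance and pairwise epistatic genetic
variances for a repeated-record trait — the motivating application is
litter size in pigs, where each sow contributes several litters — from
SNP genotypes and phenotypes, using a GBLUP-type mixed model:

$$
\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{f}b
 + \mathbf{Z}\mathbf{g}_A + \mathbf{Z}\mathbf{g}_D
 + \mathbf{Z}(\mathbf{g}_{AA} + \mathbf{g}_{AD} + \mathbf{g}_{DD})
 + \mathbf{Z}\,\mathbf{pe} + \mathbf{e}
$$

where $\mathbf{X}$ carries an intercept and dummy-coded parity and
contemporary-group effects, $\mathbf{f}$ is the per-individual genomic
inbreeding (proportion of homozygous SNPs) expanded to record level and
centered, $b$ is the inbreeding-depression regression (phenotype units
per unit of homozygosity), $\mathbf{pe} \sim N(0, \mathbf{I}\sigma^2_{pe})$
is the permanent environmental effect shared by an individual's records,
and $\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$.

Each genetic vector has covariance $\mathbf{G}_t\sigma^2_t$:

* $\mathbf{G}_A = \mathbf{M}\mathbf{M}'/(2\sum_i p_i q_i)$ with the
  VanRaden centered gene-content coding
  $(2-2p_i,\; 1-2p_i,\; -2p_i)$;
* $\mathbf{G}_D = \mathbf{W}\mathbf{W}'/(4\sum_i p_i^2 q_i^2)$ with the
  NOIA dominance coding under HWE $(-2q_i^2,\; 2p_iq_i,\; -2p_i^2)$;
* $\mathbf{G}_{AA} = (\mathbf{G}_A \odot \mathbf{G}_A)/
  (\mathrm{tr}(\mathbf{G}_A \odot \mathbf{G}_A)/n)$, and likewise
  $\mathbf{G}_{AD}$ and $\mathbf{G}_{DD}$ from the Hadamard products of
  $\mathbf{G}_A$ and $\mathbf{G}_D$, each rescaled so its mean diagonal
  is one.

Under Hardy–Weinberg and linkage equilibrium this parameterization is
orthogonal: adding dominance or epistatic terms leaves the definition
(and, in large samples, the estimate) of the additive component
unchanged, which is what makes reported breeding values unambiguous.
Only pairwise interactions are fitted; higher-order Hadamard powers
converge to the identity and are not distinguishable from residual
noise.

Allele frequencies are always the observed frequencies of the analyzed
genotypes, so the columns of $\mathbf{M}$ sum to zero exactly. Missing
genotypes are mean-imputed ($2p_i$) for $\mathbf{M}$, which makes them
contribute exactly zero after centering; in $\mathbf{W}$ they are set to
zero, the HWE expectation of the dominance coding, for the same
no-information-contributes-nothing reason. Genomic inbreeding is always
computed from observed calls only.

## Quality control

`apply_qc()` applies, in a fixed order that makes removal counts
reproducible: individual call rate (default $\ge 0.90$), SNP call rate
($\ge 0.90$), minor allele frequency ($\ge 0.05$), and a Hardy–Weinberg
heterozygote-excess filter
$|\hat h_i - 2p_iq_i| \le 0.15$. These defaults mirror the documented
defaults of the preprocessing tools commonly used with these models; all
four thresholds are arguments.

## Bayesian estimation

Variance components are estimated by Gibbs sampling (`gibbs_sample()`),
with scaled-inverse-chi-square priors on variances — flat by default
($S = 0$, $\nu = -2$), so each full conditional is
$(\mathrm{SS} + \nu S)/\chi^2_{\dim + \nu}$ and posterior modes are
comparable to REML — and flat priors on location effects. The reference
chain protocol is 200,000 iterations, 10,000 burn-in, thinning 100
(1900 retained samples); `chain_config(20000, 2000, 10)` is a practical
scaled-down chain for continuous testing.

Two numerical choices matter:

* **Eigenbasis sampling.** Centered genomic relationship matrices are
  near-singular along the ones vector. Inverting them (even after the
  default $10^{-6}$ ridge, which is recorded on the object) makes
  single-site updates of $\mathbf{g}_t$ nearly immobile along the
  near-null direction. The sampler therefore draws each genetic block in
  the eigenbasis of its regularized matrix,
  $\mathbf{g}_t = \mathbf{U}\mathbf{D}^{1/2}\mathbf{u}_t$ with
  $\mathbf{u}_t \sim N(0, \sigma^2_t\mathbf{I})$: one eigendecomposition
  per matrix, reused every iteration, with $O(n)$ cost per coordinate
  update.
* **Variance floor.** Draws are floored at $10^{-12}$ so a variance
  cannot become an absorbing zero state. Seeds are explicit
  (`chain_config(seed = )`) and chains are bit-reproducible.

Posterior summaries (`variance_ratios()`) report, per retained sample,
$\sigma^2_P$ as the sum of **all** fitted random components (genetic +
permanent environment + residual), and the ratios
$h^2 = \sigma^2_A/\sigma^2_P$, $d^2 = \sigma^2_D/\sigma^2_P$, and
$i^2 = (\sigma^2_{AA}+\sigma^2_{AD}+\sigma^2_{DD})/\sigma^2_P$ over the
terms present in the model; this definition is the only one under which
the per-sample ratios sum to one. Model fit is compared with the
conditional-deviance DIC (`dic()`), using Spiegelhalter's
$p_D = \bar D - D(\bar\theta)$ evaluated at the posterior means of all
location parameters and of $\sigma^2_e$; convergence is monitored
quantitatively by the effective sample size (`effective_sample_size()`),
computed with Geyer's initial-positive-sequence truncation of the
autocorrelation sum, rather than by visual trace inspection.

## Prediction and forward validation

`solve_gblup()` solves the mixed-model equations by a direct dense
Cholesky factorization at fixed variance components (problem sizes up to
a few thousand individuals; no iterative solver is provided), returning
fixed effects, $\hat b$, every genetic-effect vector and the permanent
environmental effects. `time_split()` partitions the records at a time
cutoff, excluding individuals with records on both sides; individuals
whose records all fall after the cutoff are the selection candidates.
`method_r()` compares candidate EBV from whole and partial data through
the bias $b_0$ (also reported in additive-SD units, using the whole-data
additive variance), the dispersion slope $b_1$, and the correlation
$\rho$; sample ($n-1$) covariances over the candidate set are used, with
$n$ in $b_0$ taken as the candidate count. `predictive_ability()`
reports the correlation and OLS slope of corrected phenotypes
$y^* = y - \mathbf{X}\hat\beta - \mathbf{f}\hat b$ on predicted
observations $\hat y = \sum_t \hat{\mathbf g}_t + \widehat{\mathbf{pe}}$
over candidate records.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_dataset()` generate the study conditions the
estimator assumes: biallelic SNPs in HWE and linkage equilibrium with
allele frequencies from Uniform(0.05, 0.95); optional per-individual
latent inbreeding $F$ (scaled Beta), realized as excess homozygosity;
2–6 records per sow; parity and contemporary-group fixed effects (SDs
0.3 and 0.5 — modest fixed-effect spread of a farm-year-month design);
and the litter-size variance targets
$\sigma^2_A = 0.84$, $\sigma^2_D = 0.17$, $\sigma^2_{AA} = 0.14$,
$\sigma^2_{AD} = 0.12$, $\sigma^2_{DD} = 0.09$,
$\sigma^2_{pe} = 0.45$, $\sigma^2_e = 7.05$, grand mean 12.7, and
inbreeding depression $b = -12.33$ (i.e. −1.23 phenotype units per 10%
homozygosity). True epistatic values are built from products of centered
M/W columns over a configurable number of random locus pairs — the same
statistical structure the estimator assumes — rather than a full
Kronecker construction. In `scaling = "exact"` mode (the default, used
by the recovery tests) every generated effect vector is rescaled so its
realized variance equals its target exactly; `"expected"` mode scales
only in expectation. Phenotypes use the *realized* genomic homozygosity
as the depression covariate, not the latent $F$.

What the simulator deliberately does **not** produce: linkage
disequilibrium, pedigree/family structure, selection, or crossbred
(non-HWE) populations. This matters for interpreting tests: simulated
individuals are genomically unrelated apart from chance identity, so
cross-individual prediction is weaker than in a real breeding
population, and the finite-sample identification of many simultaneous
variance components is harder than in the real data the model family
was developed for (see below). Passing tests demonstrate correctness of
the machinery under the stated equilibrium assumptions, not field
performance on structured populations.

## Test and verification design

The package's checks run at deliberately scaled-down problem sizes so
the whole suite completes in minutes: algebraic oracles on matrices up
to $6 \times 4$; distributional checks of the sampler against closed
forms; recovery and contrast experiments with 300–500 sows, 600–1500
SNPs and chains of 5,000–10,000 iterations (10 seeded replicates);
forward validation with 400 sows. The reference chain and the full
study scale (thousands of individuals, tens of thousands of SNPs)
remain the recommended settings for real analyses.

One caveat discovered at these scales is worth stating plainly. With
unrelated HWE/LE individuals and a few hundred sows, the diagonals of
$\mathbf{G}_{AA}$ are almost a linear function of the diagonals of
$\mathbf{G}_A$, and off-diagonal relatedness is weak; the additive and
additive-by-additive components then compete for the same
diagonal-heterogeneity signal, and under flat priors the posterior mean
of $\sigma^2_A$ shifts noticeably between the additive-only and the
full model even though the parameterization is orthogonal in the
population sense. The effect shrinks as $n$ and marker count grow. The
orthogonality check in the test suite is therefore run at the largest
scale the suite's runtime budget allows, and the dominance component —
whose identification does not suffer from this collinearity — is the
sharper orthogonality witness at small scale.

## Defaults and degenerate inputs

* Regularization $\epsilon = 10^{-6}$ on every relationship matrix
  before factorization (recorded on the object).
* Monomorphic SNPs code to zero columns and are dropped from the
  additive and dominance denominators with a warning.
* A SNP with all calls missing, or an individual with all calls
  missing, is an error naming the offender.
* Constant chains make `effective_sample_size()` return the nominal
  sample count with a warning.
* `model_spec()` enforces the nesting ladder A, A+D, A+D+AA, A+D+AA+AD,
  A+D+AA+AD+DD; the permanent environmental effect is always fitted for
  repeated records (it can be disabled programmatically for
  single-record checks).

## A small worked run

```{r example, eval = FALSE}
dat <- scenario_paper_like(seed = 1)
grms <- build_grms(dat$genotypes)
f <- genomic_inbreeding(dat$genotypes)
design <- build_design(dat$records, model_spec(), f,
                       individuals = dat$genotypes$individual_ids)
chain <- gibbs_sample(design, grms,
                      cfg = chain_config(20000, 2000, 10, seed = 1))
variance_ratios(chain)
```
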