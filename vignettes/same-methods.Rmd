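---
title: "Latent-status association testing for somatic mutations"
author: "SAME package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-status association testing for somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SAME)
```

## The problem

Somatic mutation calls are binary summaries of noisy sequencing evidence.
Unlike germline genotypes, they carry non-ignorable false-positive and
false-negative rates: a mutation may be present in only a fraction of tumor
cells (so its variant-allele fraction is far below 0.5), coverage is uneven,
and conservative caller-intersection pipelines trade false positives for
false negatives. Feeding such calls into an ordinary generalized linear
model attenuates effect estimates and costs power.

This package tests association between an outcome $Y$ (continuous or
binary) and a somatic mutation while treating the true mutation status
$S_i \in \{0,1\}$ of sample $i$ as a latent variable. The observed data per
sample are the caller's binary call $O_i$, the read depth $D_i$, and the
alternative-allele read count $A_i$. Calls are only available where
coverage is adequate: $O_i$ is missing when $D_i < d_0$ (default
$d_0 = 20$ reads, matching common calling filters).

## The mutation-level model (mSAME)

With mutation frequency $\rho_1 = P(S_i = 1)$, the observed-data
likelihood is

$$ L \;=\; \prod_{i=1}^n \sum_{s=0}^{1} \rho_s\,
   f_Y(Y_i \mid S_i = s)\; f(A_i, D_i, O_i \mid S_i = s). $$

The outcome model is a GLM, $E(Y_i) = g^{-1}(x_i^\top\alpha + S_i\beta)$:
identity link with gaussian errors (variance $\phi$) for continuous
outcomes, logit link for binary ones. The evidence factor splits by
coverage:

* **High depth** ($D_i \ge d_0$): $A_i \mid D_i, S_i, O_i$ is
  beta-binomial with one component per $(S,O)$ stratum, and
  $O_i \mid S_i$ is Bernoulli with sensitivity
  $\gamma_1 = P(O=1 \mid S=1)$ and specificity
  $\gamma_0 = P(O=0 \mid S=0)$. Components are indexed by $(S,O)$ because
  calling is itself driven by the allele counts: false-positive calls sit
  on a heavy-tailed low-VAF component, missed true mutations on a lower-VAF
  component than correctly called ones.
* **Low depth** ($D_i < d_0$): no call is available; $A_i \mid D_i, S_i$
  is beta-binomial with one component per status.

Depth itself is ancillary — its distribution does not involve $S$ — so it
cancels from every likelihood ratio and the likelihood conditions on it.

Beta-binomial components are parameterized by the mean allele fraction
$\pi$ and the intra-class correlation $\phi \in [0,1)$ (shapes
$\pi(1-\phi)/\phi$, $(1-\pi)(1-\phi)/\phi$); $\phi = 0$ degenerates to the
binomial. The shipped defaults, estimated from a colon adenocarcinoma
exome cohort, are $\pi_{00},\pi_{01},\pi_{10},\pi_{11} =
(0.001, 0.002, 0.1179, 0.3207)$ with $\phi = (0.0006, 0.3457, 0.0001,
0.1018)$ at high depth, and $\pi_0 = 0.001, \phi_0 = 0.001, \pi_1 = 0.146,
\phi_1 = 0.10$ at low depth (`defaultReadCountModel()`).

The association test is a likelihood-ratio test of $H_0: \beta = 0$,
$T = -2(\log L(\hat\theta_0) - \log L(\hat\theta))$, referred to
$\chi^2_1$. We use the printed df = 1 reference without a boundary-mixture
correction, which presumes $\rho_1$ interior to $(0,1)$ — appropriate for
mutations recurrent enough to be worth testing.

## Gene-level collapsing (gSAME)

For a gene with $p$ mutation loci, the gene-level status collapses the
per-locus latent statuses by presence: $S^g_i = 1$ iff any
$S^m_{ij} = 1$. The outcome depends on $S^g_i$ only; the evidence factors
per locus given the per-locus statuses. Conditional on $S^g_i = 1$ the
status vector ranges over $2^p - 1$ non-zero configurations, which is
intractable for large $p$; since a mutation cannot plausibly be present
without a single supporting read, loci with $A^m_{ij} = 0$ are pinned to
$S^m_{ij} = 0$ and the sum runs over the $2^{m_i}-1$ non-zero
configurations of the $m_i$ "active" loci ($A > 0$). The enumeration is
capped at $m_i \le 12$ (4095 configurations) with a clear error beyond —
above the $p = 10$ design this model targets — and an option
(`restrict = FALSE`) lifts the restriction for exact-oracle comparison on
small toys.

The conditional law of the per-locus statuses given $S^g = 1$ is modeled
as independent Bernoulli with a common inclusion probability
$q = 1 - (1-\rho_1^g)^{1/p}$, renormalized to exclude the all-zero vector.
This mirrors the generative law under which independent per-locus statuses
at rate $q$ collapse to a gene frequency of exactly $\rho_1^g$, and $q$ is
re-derived from the current $\rho_1^g$ at every EM iteration. A
locus-specific $q$ would need per-locus frequency information that a
single gene's data rarely support.

The naive gene-level comparator regresses $Y$ on the collapsed observed
call (1 if any locus call is 1). Missing calls collapse as 0; an
all-missing sample is flagged `lowCoverage` downstream, since the GLM
baseline has no other way to handle it.

## Estimation

Both models are fitted by EM over the latent status (jointly with the
configuration at gene level):

* **E-step**: posterior $w_i = P(S_i = 1 \mid \text{all data})$ from the
  current parameters.
* **M-step**: weighted GLM on the augmented design (each sample appears
  once with $s = 0$, weight $1-w_i$, and once with $s = 1$, weight
  $w_i$); $\rho_1$ updates to the mean posterior. The gaussian dispersion
  is updated in every M-step (profiling it changes nothing at
  convergence).

Initialization: $\rho_1$ by method-of-moments from the observed call
frequency through $(\gamma_1,\gamma_0)$, clipped to $(1/n, 1-1/n)$;
coefficients from the naive GLM on the observed calls. Convergence is
declared when the observed-data log-likelihood moves by less than
$10^{-8}$ (cap 1000 iterations; non-convergence is reported in the fit,
not an error). The log-likelihood trace is retained so monotonicity is
checkable on every fit. $T < 0$ from numerical noise is clipped to 0 and
noted. Sites whose posterior puts all mass on one status are monomorphic
— there is no information about $\beta$ — and return `NA` with a
diagnostic instead of a spurious p-value.

The read-count components and the call-error rates are *plug-in*
quantities estimated before association testing and held fixed during the
EM:

* **High-depth components**: samples pooled across mutations are
  classified by a two-component beta-binomial mixture on $(A, D)$
  (posterior threshold 0.5); crossing the classification with the
  observed call gives the four $(S,O)$ strata, each fitted by bounded
  quasi-Newton maximum likelihood on $(\mathrm{logit}\,\pi,
  \mathrm{logit}\,\phi)$, with $\pi$ clipped to $[10^{-4}, 1-10^{-4}]$ and
  $\phi$ to $[10^{-6}, 0.999]$. Empty strata keep the defaults with a
  warning.
* **Low-depth components**: status labels for $D < d_0$ samples are
  imputed from a mixture under the default low-depth components applied
  to their own $(A, D)$, iterated once, followed by one weighted fit per
  component.
* **Call-error rates**: per mutation,
  $\hat\gamma_1 = \sum_i w_i O_i / \sum_i w_i$ and
  $\hat\gamma_0 = \sum_i (1-w_i)(1-O_i) / \sum_i (1-w_i)$ over high-depth
  samples, where $w_i$ is the read-count mixture posterior — a
  posterior-weighted concordance between calls and count evidence,
  clipped into $(0.5, 1]$. Gene-level testing estimates these per locus,
  falling back to gene-wide pooled estimates for loci with fewer than 3
  called carriers.

These plug-in procedures are this package's own design: the stratum
labeling, the one-pass low-depth imputation and the concordance estimator
are natural choices consistent with an "estimated a priori" workflow, but
other estimators of the same quantities exist.

## The synthetic-data generator

`simulateMutationSite()` / `simulateGene()` generate data from the model's
own generative law at the exome-sequencing operating point: $n = 400$
samples; $S_i \sim \mathrm{Bern}(\rho_1)$; one standard-normal covariate;
continuous outcomes $Y_i = 1 + x_i + \beta S_i + \epsilon_i$ or binary
outcomes with $\mathrm{logit}\, p_i = -0.5 + x_i + \beta S_i$; per-mutation
mean depth from a negative binomial with mean 113 and overdispersion 3.28
(variance $\mu + \mu^2/\phi$, so SD $\approx 63.3$), per-sample depths
negative binomial around that mean with overdispersion 1.9; calls at
$D \ge 20$ with sensitivity 0.9 and specificity 0.98 (gene level:
per-locus draws from $\{0.9, 1\} \times \{0.98, 1\}$, re-drawn each
replicate); counts from the default beta-binomial components. Gene-level
statuses are generated per locus at rate $1-(1-\rho_1^g)^{1/p}$ so the
collapsed frequency is $\rho_1^g$. A `wgsMode` draws depths in a single
stage with mean 40, resembling whole-genome coverage.

Calls are simulated directly from $(\gamma_1, \gamma_0)$ rather than by
running a variant caller on synthetic reads; consequently the simulations
exercise the error *model*, not caller-specific artifacts (strand bias,
mapping error, FFPE damage, tumor purity), and passing them says nothing
about those. `runExperiment()` spawns one sub-seed per replicate from the
master seed, so all methods see identical data within a replicate and
every run is exactly reproducible.

```{r example}
cfg <- simConfig(n = 400, rho1 = 0.10, beta = 0.6, seed = 7)
sim <- simulateMutationSite(cfg)
msameTest(sim$site, sim$Y, sim$X, cfg@readCountModel,
          CallErrorModel(0.9, 0.98))
glmWaldTest(sim$site@O, sim$Y, sim$X)
```

## Numerical choices

* Beta-binomial log-pmf: `lbeta`-based closed form for $\phi \ge 10^{-4}$;
  below that the beta shapes exceed $10^4$ and the `lbeta` differences
  cancel catastrophically, so rising-factorial ratio sums are used
  instead; $\phi = 0$ dispatches to the binomial.
* All mixture sums use log-sum-exp. Zero-probability evidence (a call
  conflicting with an error rate of exactly 1) is clamped to a large
  negative log at gene level so configuration products stay finite; a
  sample dead under both gene-status branches is then detected and
  reported by sample index.
* The EM tolerance ($10^{-8}$ on the log-likelihood) is far below the
  $\chi^2_1$ resolution of the test; the LRT inherits roughly twice that
  tolerance.

## Problem sizes used in the test suite

Type-I error is checked on 1000 replicates of the $n = 400$ null design
(mutation level $\rho_1 = 0.05$; gene level $\rho_1^g = 0.10$, $p = 10$),
power and MSE orderings on 500 replicates per cell at $\beta = 0.6$,
$\rho = 0.10$, and parameter-recovery studies use 50–200 replicates.
These sizes put Monte-Carlo standard errors near 0.007 for the
calibration checks and near 0.015–0.022 for the power comparisons, which
is sharp enough to resolve the orderings being asserted.

## Known limitations

* Multi-allelic sites, strand bias, mapping quality and tumor purity are
  not modeled; the VAF components absorb purity implicitly.
* The $\chi^2_1$ reference is asymptotic; for extremely rare mutations
  (a handful of carriers) the boundary effect on $\rho_1$ can distort
  finite-sample calibration.
* Gene-level collapsing treats all loci exchangeably; functional weighting
  and pathway-level aggregation are out of scope.
* The exact-enumeration cost grows as $2^{m_i}$; genes where a sample has
  more than 12 alt-positive loci must be pre-filtered.
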