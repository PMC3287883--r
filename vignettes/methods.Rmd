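---
title: "Shrunken discriminant rules for rare-variant risk prediction: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrunken discriminant rules for rare-variant risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebrisk)
```

# The model

## Burden scores

A gene score collapses a gene's SNPs into one per-individual scalar.
`ebrisk` uses the Madsen–Browning weighted sum

$$X_{ij} = \sum_{l \in \text{gene } i} \frac{G'_{lj}}
          {\sqrt{n\,\hat q_l (1 - \hat q_l)}},$$

where $G'_{lj}$ is the minor-allele count (folded, $2-G$, when the
empirical frequency of the counted allele exceeds 0.5) and $\hat q_l$
the empirical MAF over all $n$ individuals. The weight is the inverse
binomial standard deviation of the allele count, so a singleton carries
roughly $\sqrt{n\hat q(1-\hat q)}$ times the weight of a common variant:
rare variation dominates the score by construction. MAF is estimated on
the full panel, not on controls only: in the replicated-phenotype
setting the genotypes are fixed, and a full-panel estimate keeps the
weights identical across replicates. Monomorphic SNPs are excluded
(a pseudocount alternative, $+1/(2n+2)$, is available via
`pseudocount = TRUE`); genes left with no polymorphic qualifying SNP are
omitted rather than zero-filled, so a missing column is always
distinguishable from "no burden observed".

## Z statistics and replicate correlation

For each gene the two-sample statistic

$$Z_i = \frac{\bar x_{i,1} - \bar x_{i,2}}
        {\hat\sigma_i\sqrt{1/n_1 + 1/n_2}}$$

(pooled unbiased $\hat\sigma_i$, divisor $n_1+n_2-2$) is approximately
$N(\delta_i, 1)$, with $\delta_i$ the standardized case-control
difference. With $R$ phenotype replicates drawn on one genotype panel,
$\bar Z_i$ is a better estimate of $\delta_i$ but its variance is
$(1 + (R-1)\rho)/R$: the replicates share the panel, so individuals with
high genetic liability are cases in most replicates and a gene's Z
values correlate across replicates. Under the exchangeable model
$Z_{ir} = \delta_i + \varepsilon_{ir}$, $\mathrm{Var}(\varepsilon)=1$,
$\mathrm{Cor}(\varepsilon_{is},\varepsilon_{it})=\rho$, the per-gene
across-replicate sample variance has expectation $1-\rho$ regardless of
$\delta_i$, giving the moment estimator

$$\hat\rho = 1 - \frac{1}{N}\sum_i s_i^2,$$

clipped to $[0,1]$. Standardizing,
$Z^*_i = \bar Z_i / \sqrt{(1+(R-1)\hat\rho)/R}$ has unit variance, the
scale on which shrinkage operates; shrunken values are mapped back by
the inverse factor before entering the discriminant.

## Empirical Bayes shrinkage

Genes are selected by ranking, and ranked extremes are biased away from
zero. The remedy is the posterior mean under the ensemble's own prior:
for $z \sim N(\delta, 1)$, Tweedie's formula gives

$$\hat\delta(z) = z + \frac{d}{dz}\log f(z)$$

with $f$ the *marginal* density of the z-values. $f$ is estimated by
Lindsey's method: bin the ensemble into equal-width bins (the data range
padded by one bin width), regress the counts on a degree-$J$ polynomial
of the bin midpoints with a Poisson log-link GLM, and read off
$\log\hat f$ as the fitted linear predictor. The derivative is then
analytic in the polynomial coefficients. Two closed-form limits pin the
construction down: a pure-null ensemble ($f = \phi$) shrinks everything
to zero, and a conjugate ensemble $z \sim N(0, 1+\tau^2)$ yields the
linear shrinker $z\,\tau^2/(1+\tau^2)$ — both are verified exactly in
the tests by supplying the true log-density, and approximately
(tolerance 0.2 on $|z|\le3$ at $n = 5000$) for fitted densities.

## The three rules

With shrunken effects $\hat\delta_i$, centers
$\hat m_i = (\hat\mu_{i,1}+\hat\mu_{i,2})/2$, scales $\hat\sigma_i$ and
$c_n = \sqrt{1/n_1+1/n_2}$, an individual with scores $x$ is assigned to
the case group when

$$\sum_{i \in S} \hat\delta_i\, c_n\, \frac{x_i - \hat m_i}{\hat\sigma_i}
  \;>\; \tau,$$

$S$ being the top-$K$ genes by $|\hat\delta_i|$. The three rules differ
in what "the score" is:

- **EB** uses the all-SNP burden.
- **WEB** builds a weighted burden $w_i X^n + (1-w_i) X^s$ from the
  nonsynonymous and synonymous channels. The weight
  $w_i = p_{i|s} / (p_{i|n} + p_{i|s})$ is formed from two-sided Wald
  p-values of the score coefficient in logistic regressions of disease
  on (channel score, Smoke), fitted once on the pooled training
  replicates; it lies in $[0,1]$, equals $1/2$ when the channels are
  equally associated, and approaches 1 when the nonsynonymous channel
  dominates. Genes with only one channel fall back to that channel,
  flagged.
- **JC** keeps the two channels as a bivariate feature with per-gene
  within-class correlation matrix $\hat P_i$ (clipped to
  $|r| \le 0.99$), shrinks the nonsynonymous and synonymous $Z^*$
  ensembles *separately* (they are different populations of effects —
  if the data show the nonsynonymous channel to be the informative one,
  the synonymous ensemble is simply shrunk harder), and contributes
  $\hat\delta_i^\top \hat P_i^{-1} u_i\, c_n$ per gene, ranking genes by
  $\hat\delta_i^\top \hat P_i^{-1} \hat\delta_i$. With $\hat P_i = I$
  and tied shrinkers this reduces exactly to the sum of the two
  univariate EB terms (verified to 1e-10).

Covariates (Age, Sex, Smoke — any columns of the covariate table) enter
as an unshrunk logistic linear predictor fitted on the pooled training
replicates: a handful of strong, deliberately chosen variables is not
the large-ensemble regime that justifies shrinkage. The decision
threshold is $\tau = \log(n_2/n_1)$ — the prior-odds correction for
class imbalance — when no covariate model is attached; with covariates
the logistic intercept already encodes prevalence, so $\tau = 0$. The
spec source leaves open whether the imbalance term also applies with
covariates present; folding it into the intercept is the choice made
here, because applying both would double-count prevalence.

## Cross-validated gene number

Replicates are split at random into train/test/validation sets
(reference design 50/50/100 of 200). All estimation — Z, $\hat\rho$,
the shrinkage map, ranking, centers/scales, covariate model — happens on
the training replicates. The gene-number grid (default 1..50) is scored
by mean misclassification over the test replicates, $K^*$ taken at the
minimum with ties broken toward smaller $K$ (parsimony). The $K^*$ rule
is then assessed once on the validation replicates; means and standard
errors over repeated splits use the split-level values
($\mathrm{sd}/\sqrt{n_\text{splits}}$). The per-split minimum (rather
than minimizing an averaged curve) is used because each split is an
independent repetition of the whole selection procedure. The no-leakage
property is tested by permuting a validation replicate's labels and
checking that the test-error curve, $K^*$ and scores are bit-identical.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_bins` | adaptive: `min(120, max(30, n/5))` | Lindsey histogram bins; 120 at the reference scale of thousands of genes |
| `degree` | adaptive: 5 for $\ge 500$ z-values, down to 3 | Lindsey polynomial degree $J$ |
| `rho` | estimated | override for the inter-replicate correlation (required meaningfully at $R = 1$, where 0 is used) |
| `K_grid` | 1..50 | candidate gene numbers |
| `split_sizes` | ~1/4, 1/4, 1/2 of replicates | train/test/validation counts |
| `pseudocount` | off | $+1/(2n+2)$ MAF stabilizer instead of excluding monomorphic SNPs |

The adaptive Lindsey defaults are an implementation lesson: the
reference setting (120 bins, degree 5) is tuned to ensembles of
thousands of z-values; on small ensembles (a few hundred genes) a
degree-5 tail wiggles enough to *anti-shrink* the extreme values that
ranking cares about. The defaults therefore degrade smoothly with the
ensemble size and reach the reference values at scale; both knobs can be
forced.

A second estimation-accuracy caveat is recorded here because a test
encodes it: on a bimodal mixture ensemble (90% null, 10% shifted by 3),
the fitted Tweedie correction at the high-curvature point $z = 3$ is
accurate to about $\pm 0.25$ (degree 7, $n = 5000$), not the $\pm 0.15$
one might hope for; the exact-density limits are exact, so this is
purely histogram-estimation noise in $d\log f/dz$ where $f$ is small.

# The synthetic world

The generator emulates the *structure* that the method's corrections
exist for, with every parameter stated once:

- **Panel**: default 697 individuals, 500 genes of 1–40 SNPs (uniform),
  60% nonsynonymous.
- **MAF spectrum**: Beta(0.2, 30) truncated to $[1/(2n), 0.5]$, giving
  ~60% of polymorphic SNPs below empirical MAF 0.01 and ~6% above 0.05
  at $n = 697$ — the rare-skewed profile of mini-exome panels. (A
  flatter Beta(0.2, 2) spectrum was considered and rejected: after
  truncation at $1/(2n)$ it leaves only ~28% of SNPs below MAF 0.01,
  contradicting the rare-dominated world it was meant to describe.)
- **Genotypes**: Binomial(2, MAF) i.i.d. across individuals;
  independent SNPs by default, with an optional within-gene Gaussian
  copula (`ld_rho`) to exercise the correlated-channel premise of the
  JC rule.
- **Phenotypes**: liability threshold. $\eta$ = covariate terms
  (Age per SD, Sex, Smoke) + per-causal-gene effect × standardized
  nonsynonymous burden; per replicate, disease = $\eta + N(0,1)$ noise
  exceeds the threshold that solves
  $\text{mean}_j \Phi(\eta_j - t) = \text{prevalence}$ (default 0.3,
  the unbalanced ~30% case fraction of the reference data). Fixed
  genotypes/covariates plus redrawn noise is exactly the mechanism that
  produces $\rho > 0$; with all effects zero the replicates share
  nothing and $\hat\rho \approx 0$ (both are tested).
- **Defaults for effects**: 5 causal genes at liability effect 1.5 on
  the standardized nonsynonymous burden; covariate coefficients
  (0.5, 0.25, 0.5) per (SD of Age, Sex, Smoke), making covariates
  collectively dominant as in the reference data.

What the generator does *not* emulate: linkage disequilibrium between
genes, haplotype structure from real populations, pedigrees,
multi-allelic sites, genotyping error, and any particular real gene's
architecture. A green recovery test therefore establishes that the
pipeline works when the model's assumptions hold — independent
rare-variant signal concentrated in a burden — not that it would rank
real disease genes correctly.

Choices fixed for the acceptance worlds (before measurement): the null
calibration world attaches the covariate model to noise covariates
(calibration of the full stack, scaled to $n = 400$, 300 genes, $R=12$
for runtime — null calibration is size-insensitive); the signal-recovery
and ordering worlds use gene-only rules with zero covariate effects so
the metrics reflect the genetic pathway; the WEB-vs-EB ordering world
uses effect 1.0 rather than 1.5 so the EB baseline sits below the AUC
ceiling and the ordering is informative.

# Numerical choices

- Polynomial fitting uses centered/scaled midpoints; the derivative is
  transformed back analytically.
- Tweedie evaluation clamps inputs beyond the fitted range ± one bin
  width (warning) rather than extrapolating a high-degree polynomial.
- Degenerate genes (zero pooled SD in any training replicate) are
  dropped from ranking, not patched.
- Quasi-separated logistic fits in the WEB weights (|coef| > 15 or
  SE > 30) are flagged and given p = 1, shrinking the gene toward an
  uninformative weight rather than an infinite one.
- Gene ranking ties break by gene id (lexicographic) for determinism;
  test-error ties break toward smaller $K$.
- $c_n$ and $n_1, n_2$ are averaged over training replicates when more
  than one is used; centers and scales are per-replicate estimates
  averaged the same way.
- All simulation entry points take a seed and restore the caller's RNG
  state, so library use never perturbs a user's stream.

# Known limitations

- No per-gene heterogeneous $\rho$; a single exchangeable correlation is
  assumed across genes and replicate pairs.
- No empirical-null re-centering of the z ensemble (the theoretical
  N(0,1) null is assumed, consistent with the variance-1 construction);
  data with inflation would need that extension.
- No gene–gene covariance beyond the within-gene 2×2 channel block.
- The small-sample normal approximation for Z is used throughout; no
  t-correction.
- $R = 1$ provides no information about $\rho$; the rules run (with
  $\rho$ irrelevant at $R = 1$) but replicate-correlation machinery is
  inert.
- Burden weights beyond the syn/nonsyn split (CAST, SKAT-style kernels,
  functional scores) are out of scope.
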