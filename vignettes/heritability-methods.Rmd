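---
title: "Estimating components of heritability with heritkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating components of heritability with heritkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heritkit)
```

## The model

heritkit estimates the components of heritability of a quantitative or
dichotomous trait in cohorts that mix closely and distantly related
individuals. The engine is the standard variance-component mixed model: a
phenotype vector $y$ (standardized to mean 0, variance 1 for quantitative
traits) is modeled as multivariate normal,

$$y \sim N(X\beta,\ V), \qquad
  V = \sum_c \sigma^2_c K_c + \sigma^2_e I ,$$

where $X$ holds fixed-effect covariates (age, sex, region in the
conventional setup), each $K_c$ is an $n \times n$ genetic relationship
matrix, and the variance components are estimated by restricted maximum
likelihood. On a standardized trait, $\sigma^2_c / \sum_d \sigma^2_d$ is
the proportion of phenotypic variance attached to relationship structure
$K_c$ — a heritability parameter.

Four relationship matrices are supported, and the choice of matrix decides
*which* heritability is estimated:

* **IBS** (`build_ibs()`): the allele-frequency-standardized genotype
  correlation. Entry $(j,k)$ is
  $\frac{1}{N}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$ with allele
  counts $x$ and in-sample frequencies $p_i$; the diagonal is one plus an
  inbreeding estimate. On *unrelated* samples, a single-component fit with
  this matrix estimates the SNP heritability $h^2_g$ — the variance tagged
  by the genotyping platform.
* **Thresholded IBS** (`threshold_ibs()`): the IBS matrix with every
  off-diagonal entry at or below $t$ set to zero (diagonal untouched). The
  surviving large entries are good estimates of pairwise IBD, so a fit with
  this matrix approximates the *total* narrow-sense heritability $h^2$
  without phase information. The default $t = 0.05$ errs on the side of
  caution; $t = 0.025$ is also unbiased in the designs validated here,
  while $t = 0$ shows a marked downward bias.
* **IBD** (`build_ibd()`): the realized fraction of the genome shared
  identical by descent for each pair, with single-chromosome sharing
  weighted 1/2 (full siblings average 0.5). The diagonal is 1 plus the
  maternal-paternal sharing fraction. A fit with this matrix estimates
  narrow-sense $h^2$ directly.
* **IBD2** (`build_ibd2()`): the fraction shared on *both* chromosomes
  (siblings 0.25 in expectation, parent-offspring 0); diagonal exactly 1.
  Paired with IBD in the ADE model, its parameter absorbs the combined
  effect of shared environment, dominance, and epistasis — all of which
  load preferentially on pairs that share both chromosomes.

IBS-type matrices are mean-centered (off-diagonal grand mean subtracted)
before fitting; IBD-type matrices are not. Where the order of centering
and thresholding was left open, heritkit thresholds first and centers the
thresholded matrix; centering only shifts entries by a grand mean, so a
different order changes nothing material, and the `centered` flag plus an
exposed `center_ibs()` keep the choice inspectable. Whether the diagonal
participates in "mean zero" was also open; heritkit leaves the diagonal
untouched, because shifting it would rescale the variance-component
interpretation.

### The joint model

With relatives in the sample, the raw-IBS fit is a hybrid: its large
entries carry pedigree information (pushing the estimate toward total
$h^2$) while its small entries only carry linkage-disequilibrium
information (pulling toward $h^2_g$); the estimate provably sits between
the two. The joint model (`estimate_joint()`) resolves this by fitting two
components — a close-relative matrix (thresholded IBS, or IBD when
available) *plus* the full IBS matrix. The parameter on full IBS is
$h^2_g$; the sum of both genetic proportions is the total $h^2$. This uses
every individual: no relative-pruning is needed, and the package's
validation shows pruning attains the same mean with a substantially larger
sampling variance.

### REML, in detail

`fit_reml()` maximizes the restricted log-likelihood
$L_R = -\frac12[\log|V| + \log|X'V^{-1}X| + y'Py]$ with
$P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$, using average-information
(AI) updates: the score for component $c$ is
$-\frac12[\mathrm{tr}(PK_c) - y'PK_cPy]$ and the AI matrix entry $(c,d)$
is $\frac12\,y'PK_cPK_dPy$. Numerical choices:

* starting values $\sigma^2_c = \mathrm{var}(y)/(C+1)$; the first iteration
  is an EM step (stable far from the optimum), then AI steps with
  step-halving;
* under the default non-negativity constraint, components pushed below
  zero are pinned at $10^{-6}\mathrm{var}(y)$ and the AI system is
  re-solved over the free components (an active-set step) — without this,
  fits near a boundary stall short of the constrained optimum;
* if no damped AI step increases $L_R$, an EM step (guaranteed ascent) is
  taken instead;
* convergence requires the relative change in $L_R$ to fall below `tol`
  (default $10^{-6}$) on two consecutive iterations, so a slow crawl along
  a constraint boundary is not mistaken for convergence; hitting
  `max_iter` (default 100) flags the fit rather than raising an error;
* standard errors come from the inverse AI matrix at the optimum, and
  proportion (heritability) standard errors by the delta method with the
  full covariance of the variance estimates.

The non-negativity constraint is the default because variance components
are variances; the unconstrained mode exists because a bounded estimator
has a truncated sampling distribution, which biases *means* of dispersed
estimators and distorts boundary null distributions — the validation
suite uses it wherever an unbiasedness claim is tested.

`lrt()` compares nested fits with $\Lambda = 2(L_{full} - L_{null})$
clamped at zero against a $\chi^2_{df}$ upper tail. When a variance
component is tested at the boundary of its space the plain $\chi^2_1$
reference is conservative; the $\frac12\chi^2_0 + \frac12\chi^2_1$ mixture
is exposed as an option, with the plain reference kept as default to match
the convention of the cohort analyses this package mirrors. A full fit
more than trivially *below* its null (relative to the likelihood scale)
triggers a refit warning; a pinned boundary fit tying the null to within
rounding does not.

### Dichotomous traits and the liability scale

Dichotomous traits are fitted as 0/1 on the observed scale and converted
with `observed_to_liability()`:
$h^2_l = h^2_o \cdot \frac{K(1-K)}{z^2}\cdot\frac{K(1-K)}{P(1-P)}$, where
$K$ is the population prevalence (estimated by `estimate_prevalence()` as
the case fraction of the whole cohort), $P$ the case fraction in the
analyzed sample and $z$ the standard normal density at the liability
threshold. The full ascertainment correction (second factor) applies to
the SNP component $h^2_g$; no correction exists for the ascertainment of
*affected relatives* that family-based components are exposed to, so
liability-scale totals are flagged as upper bounds. Where it was unclear
whether $P$ should be recomputed per component, the cohort-wide case
fraction is used for all components.

### Pedigree relationship classes

`class_h2()` implements the correlation-based estimator: the Pearson
correlation of a phenotype across pairs of one relationship class, divided
by the class's expected IBD fraction (2× for siblings or parent-offspring,
4× for half-siblings/grandparent-grandchild/avuncular, 8× for first
cousins). Each pair enters once in each order so the estimate cannot
depend on member labeling. No per-trait standard error is attached —
pairs within a class are themselves related in complex ways — so
uncertainty is always aggregated across traits (`class_average()`,
`compare_classes()` with its across-trait Wald test). Covariates are
removed beforehand by linear residualization (`residualize()`), the
simplest mechanism consistent with "conditioning on" them. Maternal and
paternal half-siblings are pooled into one class.

## The simulator and what a green test establishes

`simulate_cohort()` realizes the validation world: binary haplotypes drawn
per SNP with frequencies uniform on (0.05, 0.5), 5,000 observed + 5,000
unobserved SNPs, and 700 pairs per cohort by default. A pair with IBD
fraction $x$ is created by copying the first member's haplotypes onto the
second at a uniformly chosen subset of positions spanning both panels. The
phenotype is additive over all SNPs — standardized genotypes times
$\sqrt{h^2_k/m_k}$ per panel ($\sqrt{0.5/10000}$ at the defaults) — plus
normal noise of variance $1 - h^2_{obs} - h^2_{unobs} = 0.5$, giving unit
phenotypic variance, heritability 50%, half from the observed panel.

Design choices in the generator:

* Copying **both** haplotypes at the selected positions makes the expected
  standardized-IBS entry equal $x$ itself, consistent with labeling pair
  relatedness directly by $x$ (0.5 = sibling level); the one-haplotype
  variant (expectation $x/2$, a parent-offspring-like sharing pattern at
  $x = 1$) is available as `copy_mode = "one"`.
* A pair block may specify IBD2 separately: `c(n, 0.5, 0.25)` copies both
  haplotypes over a quarter of the genome and one haplotype over a
  disjoint half, reproducing the sibling expectation (IBD 0.5, IBD2 0.25)
  exactly. This matters because a world where IBD2 = IBD for every pair
  makes $K_{IBD}$ and $K_{IBD2}$ identical and the ADE model
  unidentifiable; ADE validation therefore mixes sibling-like and
  parent-offspring-like blocks. Note real sibling IBD2 arises from
  meiosis; the simulator's position-subset version is an idealization.
* Copied positions are an independent uniform subset per pair — sharing is
  imposed SNP-wise, not as contiguous segments (`block_copy = TRUE` exists
  for segment realism). Per-SNP effects use realized sample moments for
  standardization, so the target variance split holds conditionally on the
  drawn genotypes.
* The dominance-like effect used in ADE power checks is drawn from
  $N(0, v\,K_{IBD2})$ — every individual carries variance $v$, correlated
  within pairs at their IBD2 fraction — which is exactly the generative
  model the ADE fit assumes. The superficially simpler alternative (noise
  added only to sibling pairs) makes the model heteroskedastic by pair
  type and is not what the ADE decomposition estimates.
* All randomness flows from one integer seed with R's default generators
  pinned, so outputs are bit-reproducible across platforms;
  `replicate_study()` derives replicate seeds as `seed + replicate`.

The generator draws SNPs independently (no linkage disequilibrium), uses a
uniform allele-frequency spectrum, and imposes relatedness only within
disjoint pairs. A green parameter-recovery test therefore establishes that
the estimators recover the variance decomposition they define — it does
not establish robustness to LD structure, population stratification,
assortative mating, or real IBD-segment geometry. The split-chromosome
mode (`split_chromosome_phenotype()`) covers part of that gap when real
genotypes are supplied: causal variants every 500th SNP along even
chromosomes stand for the genotyped panel and along odd chromosomes for
untagged variation, with realized (not nominal) genotypic variances
defining the truth. Causal picking starts at the first SNP of each parity,
so a spacing larger than a parity's SNP count still yields one causal
variant rather than an empty set; a parity with no SNPs at all warns.

## Validation experiments and their tolerances

The test suite re-runs the package's own validation experiments at reduced
replicate counts (the published versions of these designs used 1000
replicates; the heavy designs run at 25 in the test suite and 50 in
`scripts/acceptance.R`, roughly 10 minutes each on one CPU). All
recovery checks use 3 Monte-Carlo-standard-error bands, so fewer
replicates mean honestly wider bands, not looser science:

* standard design — mean $\hat h^2_{IBD}$ within 3 MC s.e. of 0.50; joint
  $\hat h^2_g$ within 3 MC s.e. of 0.25; observed-SNP share of total near
  50%;
* mixed design (350 pairs at 0.5 + 350 at 0.025) — IBD and thresholded-IBS
  means within 0.02 of each other; the raw-IBS estimate bracketed between
  the joint model's two estimates in at least 90% of replicates; pruning
  at $K_{IBS} > 0.025$ reproducing the joint mean with a larger empirical
  s.d. (both arms unconstrained, see above). With 5,000 SNPs the IBS noise
  s.d. is $\approx 0.014$, so this filter also catches noise pairs and
  discards most of the cohort — far more aggressive than the same
  threshold on a dense genotyping array, which makes the variance penalty
  of pruning especially visible;
* optimizer — the fitted optimum within one 0.005 grid cell of a dense
  eigendecomposition-based grid search on ten random 40-sample problems;
  analytic scores within $10^{-5}$ relative error of central finite
  differences;
* liability conversion — equal to within $10^{-6}$ of a numerically
  integrated threshold model at prevalences 0.01-0.5;
* ADE null — 100 additive-only replicates (sibling-like plus
  parent-offspring-like pairs, n = 700): the 1-df LRT rejection rate at
  0.05 not significantly above nominal, and the empirical CDF of p-values
  never meaningfully above the uniform diagonal (the bounded fit piles
  mass at $\Lambda = 0$, so the test is conservative by construction).

One stated power figure is *not* reproduced: a dominance-like variance of
0.3 carried only by sibling-like pairs gives the 1-df LRT little power
even at n = 1400 (the additive/dominance contrast rests on the
$0.25\,\sigma^2_d$ covariance gap between sibling-like and
parent-offspring-like pairs), although the component estimate itself is
unbiased. The suite asserts unbiased recovery and aggregate significance
instead.

## Practical notes

* Missing genotypes are excluded from per-SNP frequency estimation and
  mean-imputed ($2p_i$, a zero standardized score) for relationship-matrix
  construction. Monomorphic SNPs must be removed first
  (`drop_monomorphic()`); frequencies are always recomputed in-sample
  after subsetting.
* Sample alignment between phenotypes, genotypes and relationship matrices
  is by identifier, never by position.
* GCTA-format binary GRMs (`read_grm_gcta()`/`write_grm_gcta()`) use
  4-byte reals, so round-trips are exact only to single precision.
* Thresholding zeroes entries *at or below* $t$ (so $t = 0$ removes the
  mean-zero distant entries, as intended); the threshold is recorded in
  the result.
* Minimum pair counts for class estimators (e.g. 100 pairs) are study
  design filters, not estimator properties; `class_h2()` exposes them as a
  configurable warning only.

## A worked example

```{r example, eval = FALSE}
spec <- simulation_spec(seed = 1)   # 700 pairs, 5000 + 5000 SNPs, h2 = 0.5
sim <- simulate_cohort(spec)

K_ibd <- build_ibd(sim$true_ibd, sim$phenotype$id)
K_ibs <- build_ibs(sim$observed)

# total narrow-sense heritability from the true IBD matrix
estimate_h2(trait ~ age + sex + region, sim$phenotype, K_ibd)

# joint total + SNP heritability from thresholded IBS + IBS
estimate_joint(trait ~ age + sex + region, sim$phenotype,
               threshold_ibs(K_ibs, 0.05), K_ibs)

# the same machinery through the modelling interface
fit <- greml(trait ~ age + sex + region, sim$phenotype,
             kinship = list(ibd = K_ibd))
summary(fit)
```
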