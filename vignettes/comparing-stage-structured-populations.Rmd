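---
title: "Comparing stage-structured populations by resampling individual histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing stage-structured populations by resampling individual histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcompare)
```

## The inferential problem

A stage-structured population observed over one projection interval yields a
single projection matrix and hence a single value of each demographic
parameter: the asymptotic growth rate $\lambda$, the net reproductive rate
$R_0$, the generation time $T$, the stable stage structure (SSS) and the
reproductive value (RV). Comparing two populations therefore looks like
comparing two lone numbers. The resolution is to view each parameter not as a
lone number but as a function of the fates of the sampled individuals — just
as a sample mean is a function of sampled measurements. Each individual
contributes one *life history*: its initial stage, its fate (destination
stage or death), and the recruits it produced. Resampling those histories
quantifies the parameter's sampling uncertainty, and reallocating pooled
histories between populations builds the null distribution of any
between-population difference.

`popcompare` implements this programme: deterministic matrix demography,
randomization tests (global, pairwise and planned group comparisons),
bootstrap confidence intervals, one-way life table response experiments
(LTRE), and resampling-based power analysis, for populations supplied either
as raw individual records or as $F$/$U$ matrix pairs with known individual
counts.

## Data model

The transition matrix $U$ holds survival/growth probabilities (column
deficits from 1 are deaths); the fecundity matrix $F$ holds expected recruits
per individual per interval; $A = F + U$. A `history_table` stores one row
per individual; `project_matrix()` tabulates $u_{ij}$ as observed fate
frequencies and $f_{ij}$ as mean recruit production per stage-$j$ individual.
`histories_from_matrix()` inverts this (largest-remainder rounding, ties
broken toward survival then lower destination stage), which is what makes
matrix input usable: a matrix without its individual counts is not usable for
inference, because any two non-identical matrices become "significant" once
enough individuals are assumed.

Two conventions deserve explanation:

* **Census timing.** Under a prebreeding census a recruit is a newborn that
  survived to the next census; under a postbreeding census it is a newborn
  counted at breeding, produced after the parent survived the interval and
  expressed the fertility of its destination stage. In both cases the
  empirical fecundity entry $f_{ij}$ is total recruits credited to
  individuals *starting* in stage $j$ divided by $n_j$: crediting recruits to
  the parent's destination-stage column while dividing by initial-stage
  counts would mix denominators from different censuses (and divides by zero
  whenever a destination stage had no entrants). The census label is carried
  as metadata describing what a recruit count means, not as a switch on the
  arithmetic.
* **Anonymous reproduction (type 1).** When parents are unidentified,
  individual histories carry no recruit counts; a population-level recruit
  total per recruit stage is stored instead, together with the declared
  reproductive stages. Fecundity is the total divided by the number of
  reproductive individuals summed *across* the reproductive stages, assigned
  equally to each reproductive-stage column — dividing each column by its own
  stage count would multiply the implied recruit total by the number of
  reproductive stages. With one reproductive stage (the common case) the two
  rules coincide. Under permutation, pooled totals are re-credited to groups
  in proportion to their reproductive head-counts.

## Test statistics and the randomization test

Scalar parameters ($\lambda$, $R_0$, $T$) use
$d_w = |x_1 - x_2|$ (pairwise) and $d_g = \sum_i (x_i - \bar x)^2$ (global).
Vector parameters (SSS, RV, and the composition of distinct histories) are
probability vectors and use the Keyfitz distance
$D_w = \tfrac12 \sum_j |p_{1j} - p_{2j}|$ and its global analogue
$D_g = \tfrac{1}{2(n-1)} \sum_j \sum_i |p_{ij} - \bar p_{\cdot j}|$, both in
$[0, 1]$. For $n = 2$, $D_g \equiv D_w$ and $d_g \equiv d_w^2/2$.

The null hypothesis is a common origin of individuals: pooled histories are
reallocated without replacement to groups of the original sizes, the
parameter re-extracted per group, and the statistic recomputed. The p-value
is the proportion of replicates *strictly greater* than the observed
statistic, without the $+1/(B+1)$ correction — the convention is a design
choice, fixed so that reported p-values are plain exceedance proportions;
the add-one variant differs by at most $1/B$. All tests are two-tailed by
construction: the statistics are nonnegative distances that fold both tails
into the upper one. No multiplicity correction is applied; planned
comparisons report the number of tests performed and flag nonorthogonal
contrast sets.

Distinct histories are enumerated canonically (initial stage, then fate with
death last, then the recruit vector lexicographically) across all groups
before any permutation, so per-replicate composition vectors stay aligned
and results are reproducible across platforms.

**Stratification.** Under a fixed-per-stage sampling design the per-stage
counts are set by the experimenter, so the bootstrap resamples within
initial-stage strata. Permutation is stratified under the same condition and
for the same reason — an unstratified permutation would destroy the
experimentally fixed stage counts — with `stratify = FALSE` in the
`resampling_plan` as an escape hatch, since one could also argue that the
null of a common origin licenses free reallocation.

**Undefined replicates.** Generation time is undefined at replacement
($\lambda = 1$: $T = \ln R_0 / \ln \lambda$ divides by zero) and $R_0$ is
undefined when a permuted group's transition matrix traps individuals
(spectral radius 1). Such replicates are skipped and counted; results with
more than 10% skips are flagged unreliable rather than silently reported.

## Confidence intervals

`bootstrap_ci()` resamples histories with replacement (stratified under
fixed designs), re-extracts the parameter, and reports percentile intervals
at 90% and 95% plus the simulated median. The percentile method with
linearly interpolated order statistics (the default R quantile definition,
type 7) was chosen as the minimal method consistent with reporting a
"simulated median"; bias-corrected variants are possible future work. Random
sampling yields wider intervals than a fixed-per-stage design on the same
data, because stage composition is then itself resampled.

## The SSS-distance test and its calibration

Under random sampling the observed stage proportions estimate the population
structure, and their Keyfitz distance $\Delta$ to the fitted SSS measures
how far the population sits from stationarity. Significance is assessed by
bootstrap: each replicate recomputes both the resampled stage proportions
and the resampled model's SSS, and $p = \Pr(\Delta^* > \Delta)$. There is
no single canonical construction for this null, and the chosen formulation
has a knowable property: $\Delta^*$ carries the observed discrepancy *plus* fresh
resampling noise, so it stochastically dominates $\Delta$ and p-values
concentrate well above 0.5 when the population truly sits at its SSS. The
test is therefore conservative — it will not spuriously reject — and the
test suite checks exactly that property rather than uniformity. Under a
fixed-per-stage design the distance is meaningless (the sampled structure is
an artifact of the design) and the function refuses, as does the `describe`
report, with an explanation.

## LTRE

Both one-way designs decompose variation in $\lambda$ with sensitivities
$s_{ij} = v_i w_j / \langle v, w \rangle$:

* fixed: $c^{(m)}_{ij} = (a^{(m)}_{ij} - \bar a_{ij})\,
  s_{ij}\!\big(\tfrac12 (A^{(m)} + \bar A)\big)$ against the grand mean
  matrix (or a designated control via `reference`); sensitivities at the
  half-way matrix rather than at $\bar A$ because the midpoint evaluation
  cancels the leading curvature term, and the reported residual
  $\lambda^{(m)} - \lambda(\bar A) - \sum c^{(m)}_{ij}$ then shrinks
  quadratically as matrices converge;
* random: $V(\lambda) \approx \sum \mathrm{cov}(a_{ij}, a_{kl})\,
  s_{ij} s_{kl}$ with covariances across populations (denominator $n-1$,
  hence at least three populations) and sensitivities at the mean matrix.

## Power and sample-size scaling

`estimate_power()` follows the two-distribution construction: the null
distribution from permutation, a critical value at the empirical
$(1-\alpha)$ quantile (`sorted[ceiling((1-alpha) B)]`, leaving out the
fraction $\alpha$ of largest null replicates; ties count as non-rejection,
matching the strictly-greater p-value convention), and the alternative
distribution from resampling each population independently with replacement;
power is the proportion of alternative replicates strictly above the
critical value.

Two properties of this estimator are worth knowing. First, it is a
*post-hoc* power estimate: the alternative distribution is centred on the
realized between-sample difference, so for two independent samples from the
same process the expected "power" exceeds $\alpha$ substantially — the
realized chance difference is treated as signal. Power at an exactly zero
effect is obtained from two identical history collections, where the
calibration study in the test suite finds the estimate close to $\alpha$
with a small positive bias of order $1/n$ (the bootstrap alternative is
slightly wider than the permutation null at $n = 50$).

`scaling_analysis()` explores sample size by inflating every population by
20% per step ($1.2^k$, step 0 = original data) while holding the realized
history composition fixed (`scale_counts()`, largest-remainder rounding of
history counts). This is the deliberate idealization of "what if more
individuals had been sampled and identical vital rates obtained": a real
larger sample would show a different realized composition, so the curves
indicate approximate sizes needed to detect the *realized* difference, no
more. Expected behaviour — p-values falling, power rising, CI widths
shrinking as $n^{-1/2}$ — is verified in the acceptance suite.

## The synthetic-data generator

`vital_rate_spec()` + `simulate_history_table()` draw each individual's fate
from its stage's multinomial fate distribution and recruit counts from
Poisson distributions (or fixed integers for deterministic fixtures).
Poisson recruitment is the simplest overdispersion-free choice; the
inferential machinery never assumes it, since it resamples observed
histories. Under `sampling = "random"` the realized stage counts are
themselves multinomial around the declared composition; under
`"fixed_per_stage"` they are exact. The generator emulates single-interval
stage-fate-recruit data only: no density dependence, no environmental
stochasticity, no observation error, no overdispersed or correlated
recruitment, and survival independent of reproduction within an individual.
Calibration results obtained under it therefore demonstrate internal
consistency of the resampling machinery, not robustness to those real-data
features.

The simulation studies in the test suite use a three-stage
juvenile/subadult/adult life cycle (juvenile survival 0.5 with promotion
0.3, subadult promotion 0.35, adult persistence 0.65, adult fecundity 2,
$\lambda \approx 1.04$) with $n = 50$ individuals (25/15/10) per population
for test calibration, $n = 200$ for interval coverage, and $n = 100$ per
population for the size-scaling study; replicate counts are 999–2,000 per
analysis and 500 datasets per calibration. These sizes were chosen to keep
Monte-Carlo error around binomial expectations for the checks involved.

## Numerical choices

* Dominant eigenvalue: eigenvalues with $|\mathrm{Im}| < 10^{-9}$ count as
  real; the maximum real part among them is dominant. A non-simple dominant
  root (e.g. the identity matrix) averages the tied eigenvectors with a
  warning; a fully complex dominant pair falls back to the real part of the
  largest-modulus eigenvalue, also with a warning.
* Eigenvectors are sign-corrected to be nonnegative, entries below
  $10^{-12}$ zeroed, and normalized to sum to 1 before use.
* $U$ column sums may exceed 1 by at most $10^{-9}$; larger violations are
  errors (negative death probabilities), not warnings.
* Largest-remainder apportionment breaks remainder ties toward survival,
  then toward the lower destination stage, so reconstructions and count
  scaling are deterministic.
* One RNG stream per top-level resampling call, seeded from the plan;
  replicates consume it sequentially; scaling steps derive per-step seeds as
  `seed + 7919 k` (kept below $2^{31}$). Identical seed and inputs give
  bit-identical results.

## Known limitations

Histories span exactly one projection interval; there is no parentage
inference, no transient/stochastic dynamics, no two-way or regression LTRE,
no one-tailed tests, and no built-in multiplicity correction. Populations
being compared must share stage set, data type, census and sampling design.
Confidence intervals for sensitivities and elasticities are not produced
(those matrices describe the model, and are not used to compare
populations). Heterogeneous sampling uncertainty between populations can
inflate apparent differences, as in ordinary tests under variance
heterogeneity; no correction is attempted.
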