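# popcompare

Statistical comparison of demographic parameters among stage-structured
populations, for ecologists and demographers who have one projection
interval of data per population — either raw individual records or
fecundity/transition matrix pairs with known sample sizes — and who want
honest inference rather than eyeballed matrix differences.

## The idea

A population observed over one projection interval is a collection of
individual *life histories*: each sampled individual's initial stage, its
fate (destination stage or death), and the recruits it produced. Every
demographic parameter is a function of those histories, via the projection
matrix $A = F + U$:

- $\lambda$ — asymptotic growth rate, the dominant eigenvalue of $A$;
- $R_0$ — net reproductive rate, dominant eigenvalue of $FN$ with
  $N = (I-U)^{-1}$ the fundamental matrix;
- $T = \ln R_0 / \ln \lambda$ — generation time;
- stable stage structure and reproductive value — dominant right and left
  eigenvectors of $A$, as proportions;
- the composition of distinct life histories itself.

So, like a sample mean, each parameter can be resampled:

- **randomization tests** pool the individuals of the populations being
  compared and reallocate them without replacement, building the null
  distribution of a test statistic under a common origin. Scalar parameters
  use $d_w = |x_1 - x_2|$ (pairwise) or $d_g = \sum_i (x_i - \bar x)^2$
  (global); probability-vector parameters use the Keyfitz distance
  $D_w = \frac{1}{2}\sum_j |p_{1j} - p_{2j}|$ or its global analogue
  $D_g = \frac{1}{2(n-1)} \sum_j \sum_i |p_{ij} - \bar p_{\cdot j}|$.
  Planned (a priori) comparisons pool groups of populations into single
  larger populations — no parameter averaging — and test between the pools.
- **bootstrap confidence intervals** (90% and 95%, percentile method, with
  the simulated median) come from resampling histories with replacement,
  respecting the sampling design: pure random sampling resamples freely,
  fixed-per-stage designs resample within initial-stage strata.
- **one-way LTRE** (fixed and random designs) decomposes differences or
  variance in $\lambda$ into per-entry vital-rate contributions weighted by
  sensitivities.
- **power analysis** compares the permutation null distribution with an
  alternative distribution obtained by resampling each population
  independently; `scaling_analysis()` repeats everything at sample sizes
  inflated 20% per step at fixed vital rates, tracing how p-values, power
  and interval widths respond to effort.

## Worked example

Three synthetic populations (meadow, forest, coast; 3 stages, ~50
individuals each) ship with the package as plain CSV + YAML:

```r
library(popcompare)
tabs <- read_raw_data(
  system.file("extdata", "example-raw.csv",  package = "popcompare"),
  system.file("extdata", "example-meta.yaml", package = "popcompare"))

demographic_summary(project_matrix(tabs$meadow))
#> Demographic summary
#>   lambda: 1.04  R0: 1.383  T: 8.351
#>   stable stage structure: 0.5107 0.2155 0.2738
#>   reproductive value:     0.08067 0.38056 0.53877
#>   Keyfitz distance of observed structure to SSS: 0.2445
```

The meadow sample grows ~4% per interval; a newborn replaces itself 1.38
times over a lifetime, taking ~8.4 intervals to do so; and the sampled stage
distribution sits 0.24 Keyfitz units from the structure the matrix would
converge to.

```r
randomization_test(tabs[c("meadow", "forest")], "sss", mode = "pairwise",
                   plan = resampling_plan(10000, seed = 42))
#> Randomization test (pairwise), parameter: sss
#>   statistic Dw = 0.07307,  p = 0.619  (10000 replicates)

estimate_power(tabs[c("meadow", "forest")], "sss", mode = "pairwise",
               plan = resampling_plan(10000, seed = 42))
#> Power analysis (pairwise), parameter: sss
#>   critical Dw at alpha = 0.05: 0.229;  power = 0.1211

bootstrap_ci(tabs$meadow, "lambda", plan = resampling_plan(10000, seed = 42))
#> Bootstrap intervals for lambda (10000 replicates)
#>   observed 1.04, simulated median 1.048
#>   90% CI: [0.8182, 1.229]
#>   95% CI: [0.7646, 1.254]
```

The observed stable-structure difference ($D_w = 0.073$) is well inside
what random allocation of these ~100 individuals produces (p = 0.62), and at
these sample sizes the test would detect a difference of the realized size
only ~12% of the time — a nonsignificant result that power, not similarity,
explains. `scaling_analysis()` shows how many more individuals would
change that.

A thin CLI wrapping the same functions lives at
`inst/cli/popcompare.R` (subcommands `describe`, `compare`, `groups`,
`ltre`, `power`, `scale`, `simulate`; `--seed`, `--reps`, `--plots`).

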