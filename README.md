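# aukpva

Stochastic population viability analysis (PVA) for harvested great auk
(*Pinguinus impennis*) populations.

The great auk, once counted in the millions across the North Atlantic, was
extinct by the mid-19th century after centuries of industrial harvest of
birds and eggs. `aukpva` asks the demographic question behind that history:
at what constant harvest rate does an abundant, healthy seabird population
become doomed within 350 years? It is written for quantitative ecologists
and conservation modellers who want a scriptable, fully reproducible
re-implementation of a Vortex-style harvest PVA — with the calibration,
oracles and Monte-Carlo machinery exposed as ordinary R functions.

## The model in brief

* **Demography.** A two-sex, age-structured annual cycle over age classes
  1–25: monogamous breeding (one egg per pair, pairs limited by the scarcer
  sex), binomial age-specific mortality, fixed-quota harvest, ageing. The
  deterministic skeleton is a Leslie matrix whose dominant eigenvalue
  `lambda` is the asymptotic growth rate and whose eigenvector is the
  stable age distribution.
* **Harvest.** Quotas are fixed *counts* derived from the starting
  conditions: `round(rate * N0)` birds and `round(egg_rate * E_max)` eggs
  per year, with `E_max = floor(mature / 2)` the maximum annual egg
  production. For such dynamics the deterministic sustainability boundary
  sits near a quota of `N0 * (lambda - 1)`.
* **Density dependence (optional).** All mortality rates are multiplied by
  `0.5 + 0.5 * N / N0` (clamped to `[0.5, 1]`): natural mortality relaxes
  linearly to one half as density falls.
* **Extinction.** A replicate is extinct when only one sex remains;
  `P(extinction)` is the fraction of extinct replicates among (by default)
  100, with binomial standard error.
* **Calibration.** The under-determined mortality schedule (first-year,
  juvenile, adult) is pinned by bisection against printed constraints: an
  effective growth rate of 1.100 under the standard 5% egg quota and a
  stable-age mature fraction near 0.514.

## Worked example

```r
library(aukpva)

pre <- conservative_preset()   # calibrated, deliberately optimistic settings
pre
#> 'conservative' preset: lambda = 1.10475 (effective 1.10000 under a 5% egg quota)
#>   mature fraction 0.5382, first breeding age 5
#>   mortality: q0 0.350, juvenile 0.125, adult 0.01049, max age 25
```

A population of 2 million birds grows almost 10% a year under these
settings. Now harvest 10.5% of the starting size annually plus 5% of the
maximum egg production, with density-dependent mortality relief:

```r
scn <- scenario(2e6, 0.105, 0.05, dd = TRUE, replicates = 20, seed = 1,
                egg_max = 513766)
extinction_probability(scn, pre$life_table, pre$breeding)
#> P(extinction within 350 years) = 1.00 (SE 0.000, 20/20 replicates)
#>   quotas: 210,000 birds/yr, 25,688 eggs/yr
```

Every replicate is extinct — 210,000 birds a year outruns the population's
maximum growth increment even with mortality relief, so collapse is
certain, typically completing within 30–50 years. The deterministic
threshold and the Monte-Carlo sweep agree on where the boundary lies:

```r
fixed_quota_threshold(pre$life_table, pre$breeding, n0 = 2e6,
                      egg_rate = 0.05, egg_max = 513766)
#> [1] 0.0931   # mean-field boundary: 9.31% of N0

template <- scenario(2e6, 0.08, 0.05, replicates = 100, seed = 777,
                     egg_max = 513766)
max_sustainable_harvest(template, rates = seq(0.08, 0.105, 0.005),
                        life_table = pre$life_table, breeding = pre$breeding)
#> Harvest-rate sweep (100 replicates/rate):
#>   rate bird_quota p_extinct n_extinct
#>   8.0%     160000      0.00         0
#>   8.5%     170000      0.00         0
#>   9.0%     180000      0.00         0
#>   9.5%     190000      1.00       100
#>  10.0%     200000      1.00       100
#>  10.5%     210000      1.00       100
#> Maximum sustainable rate: 9.0% of N0; certain extinction from 9.5%
```

So under settings biased strongly towards survival, harvest rates up to 9%
of the pre-hunting population are sustainable and 10.5% is always fatal —
quotas well below what historical sources describe. The genetic
effective-size side converts to head counts via Ne/Nc ratios:

```r
ne <- total_effective_from_female(c(2477, 19492))  # female CI, doubled
census_from_effective(ne[1], ne[2], ne_nc_ratios(0.0515, 0.403))
#> nc_lo  nc_hi
#> 12293 756971
```

The full published scenario grid is available as `auk_reference_table()`
(inputs and reference probabilities) and `auk_reference_grid()` (runnable
scenarios for `run_grid()`).

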