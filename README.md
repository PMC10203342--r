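# greenheat

Urban populations increasingly experience extreme surface heat. `greenheat`
quantifies that burden from gridded city rasters and asks a planning
question: **where should a city add vegetation to cool the most people with
the least greening?**

The package is aimed at urban-climate and environmental-health analysts
working with 1 km-class satellite products (land surface temperature,
NDVI greenness, population counts, water masks). It provides a complete,
reproducible pipeline — including a synthetic-city generator with a known
data-generating process, so everything runs and is testable without any
satellite downloads.

## The model

**Exposure.** For each city, day and night heat thresholds are the 90th
percentile of the pooled multi-year LST distribution over all pixels and
dates. Per pixel, `days_day` / `days_night` count the warm-season (3-month)
days strictly exceeding the threshold, averaged over years. Exposure is
measured in person·days:

    TE_D = days_day × population,  TE_N = days_night × population,
    TE_T = (TE_D + TE_N) / 2

**Spatial lag model.** Exceedance counts are spatially autocorrelated, so
they are modelled as

    Y = ρ W Y + X β + ε,   X = (1, NDVI, d_w),   d_w = normalized 1 / D_w²

where `W` is a row-standardized 8-nearest-neighbour weights matrix,
`ρ` the spatial autoregressive parameter, `D_w` the Euclidean distance to
the nearest water pixel, and `ε` i.i.d. Gaussian noise. Estimation is
maximum likelihood with the likelihood concentrated over `ρ` (Ord-style),
the log-determinant computed by sparse LU. Both vegetation and
water-proximity coefficients come out negative: greener, water-adjacent
pixels see fewer extreme days. An OLS baseline and k-fold cross-validation
(test R², MAE, fold-averaged coefficients) quantify what the spatial term
buys.

**Greening scenarios.** Counterfactuals raise NDVI subject to a 0.85 cap
and push the new features through the fitted models' reduced form
`(I − ρW)⁻¹Xβ`:

- *Scenario 1 (uniform)*: every pixel gains δ.
- *Scenario 2 (targeted)*: only the minimal set of highest-population
  pixels holding 80% of residents gains δ_local, where δ_local is solved
  by bisection so the exposure reduction matches Scenario 1.

The vegetation savings statistic `100·(NDVI₈₀ − NDVI_all)/NDVI_all`
compares city-wide NDVI sums after the two interventions; an increment
sweep (δ = 0.1…0.5) tabulates the whole trade-off.

## Worked example

```r
library(greenheat)

cfg  <- synthetic_config(n_rows = 24, n_cols = 24, seed = 42,
                         ndvi_range = c(0.05, 0.35))   # a dry, monocentric city
city <- synthetic_city(cfg)

exposure_from_counts(city$grid)
#> # exposure: TE_D = 1.79e+07, TE_N = 1.88e+07, TE_T = 1.835e+07 person-days; per capita 18.35 days

fit <- fit_exceedance_slm(city$grid, "days_day", w = city$w)
tidy(fit)
#> # A tibble: 4 × 3
#>   term      estimate std.error
#> 1 intercept   10.2      0.0603
#> 2 ndvi        -5.25     0.307
#> 3 d_w         -1.16     0.102
#> 4 rho          0.493    0.0560
```

The generating truth here was β = (10, −4.7, −1.2), ρ = 0.5: one 576-pixel
city recovers it to within sampling error. Each NDVI unit buys about five
fewer extreme days per season at a pixel — before the spatial multiplier
spreads the benefit to neighbours.

```r
m_night <- fit_exceedance_slm(city$grid, "days_night", w = city$w)
uni <- scenario_uniform(city$grid, fit, m_night, city$w, delta = 0.3)
uni$delta_te_pct
#> [1] -13.1

target <- select_top_population(city$grid, 0.8)
sol <- solve_targeted_increment(city$grid, fit, m_night, city$w,
                                target, uni$delta_te_pct)
sol$delta_local
#> [1] 0.376

ndvi_savings(apply_uniform_increment(city$grid, 0.3),
             apply_uniform_increment(city$grid, sol$delta_local, 0.85, target))
#> # A tibble: 1 × 2
#>   savings_formula_pct savings_pct
#> 1               -18.5        18.5
```

Reading: greening the whole city by 0.3 cuts total exposure by 13.1%. The
same reduction is available by greening only the pixels housing 80% of the
population — a larger local increment (0.376) but 18.5% less added
vegetation city-wide.

`run_pipeline(run_config(cfg), "out/")` chains all of the above —
exposure, weights, day/night fits with cross-validation, both scenarios
and the increment sweep — into one reproducible run directory.

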