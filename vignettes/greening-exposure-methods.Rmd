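---
title: "Methods: population heat exposure and targeted urban greening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population heat exposure and targeted urban greening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenheat)
```

## Scope and data model

`greenheat` analyses one city at a time as a planar grid of 1 km-class
cells (`city_grid`, a tibble subclass). Each cell carries resident
population, NDVI greenness, the distance to the nearest water pixel and
its normalized inverse-square transform, mean warm-season exceedance
counts for day and night, and water / urban-core flags. Grids are planar
with square cells; at city scale the centroid-to-centroid Euclidean
distance needs no geodesic correction. Real-data ingestion is limited to
co-registered per-variable rasters and point tables — map projection and
satellite retrieval happen upstream of this package.

## Exposure metrics

Heat thresholds are percentiles of the *pooled* LST distribution — all
pixels and all dates of the reference period together, separately for the
day and night channels. Pooling per city (rather than per pixel) makes
the threshold a property of the city's climate, so exceedance counts are
comparable across its pixels; a per-pixel variant would measure local
anomalies instead. Numerical conventions, pinned by tests:

- percentiles interpolate linearly between order statistics
  (`quantile(..., type = 7)`);
- exceedance is strict (`LST > t`); a tie does not count;
- missing retrievals never count as exceedances, and a year whose
  warm-season mask is empty is dropped from the multi-year mean with a
  warning.

Exposure multiplies mean exceedance days by resident population,
in person·days per season; the total `TE_T` averages the day and night
components. City totals are computed as `(TE_D^c + TE_N^c) / 2` so the
defining identity holds to the last bit. Per-capita exposure (days) is
the city total over city population, undefined (NA) for an unpopulated
grid. The surface-heat-island statistic compares mean LST inside the
urban core against the surrounding ring (the outer 5-cell band in
synthetic cities, standing for a 5 km rural buffer), and reports the
ring's mean NDVI alongside: across cities, a greener (cooler) surround
makes the core stand out more, so the statistic rises with rural
greenness.

Both core and ring pixels enter the regression sample; the ring
additionally serves as the rural reference. The thresholds' reference
period and the counting period are independent configuration values.

## The water-distance feature

`D_w` is the exact Euclidean distance transform of the water mask
(two-pass separable parabola algorithm), in metres. The model feature is
`d_w = 1/D_w²`, normalized per city by its maximum so `d_w ∈ [0, 1]`.
Two conventions close the definition:

- the transform diverges on water cells (`D_w = 0`); they are assigned
  the maximum raw *land* value before normalization, preserving
  "closer to water ⇒ larger `d_w`" without infinities;
- a city with no water pixel gets an all-NA feature and a `dw_excluded`
  flag; models then drop the term rather than impute it.

Normalizing per city follows from the feature being a within-city
predictor; comparability across cities is carried by per-city fits, not
by a shared scale.

## The spatial lag model

Counts are modelled as `Y = ρWY + Xβ + ε` with `X = (1, NDVI, d_w)` and
`W` a row-standardized k-nearest-neighbour matrix (`k = 8`, equal weights
`1/k`, Euclidean metric on cell centroids, distance ties broken by
ascending pixel id so grids build deterministically). `W` is stored
sparse; nothing downstream materializes a dense `n × n` matrix (dense
algebra is allowed only inside test oracles).

Estimation is maximum likelihood with the likelihood concentrated over
`ρ`: for a candidate `ρ`, `β(ρ)` and `σ²(ρ)` are the OLS solution for the
filtered response `(I − ρW)y`, and

`ll(ρ) = −(n/2)·log(2πσ²(ρ)) + log|I − ρW| − n/2`

is maximized by scalar search on `[−0.99, 0.99]` (strictly inside the
admissible interval for a row-standardized `W`; a boundary hit is flagged
non-converged). The log-determinant uses a sparse LU factorization per
candidate `ρ` by default; a dense-eigenvalue backend (one decomposition,
then `Σ log|1 − ρλᵢ|`) is available for `n ≤ 2000` and agrees with LU to
optimizer tolerance. ML with concentrated `ρ` is the canonical fit for
this model; features enter unscaled — NDVI and `d_w` are already in
[0, 1] — so coefficients read directly as "days per feature unit".
Standard errors are basic asymptotics (OLS-style for `β` at the fitted
`ρ`; numerical curvature of the concentrated likelihood for `ρ`).

Cross-validation partitions pixels at random into k folds (deterministic
by seed). Each fold's model is fitted with `W` restricted to the training
subgraph (rows re-standardized; pixels isolated by the restriction keep a
zero row). Held-out pixels are predicted through the *full-graph* reduced
form with the training coefficients — the held-out response never enters
its own prediction, while the graph geometry does. R² is `1 − SSE/SST`
on the evaluation set. The arithmetic mean of per-fold coefficient
estimates becomes the scenario engine's working coefficient set.

## The scenario engine

The baseline exposure `TE⁰` is the *model-predicted* exposure on the
observed features, not the observed counts: both scenarios then differ
from the baseline only through the counterfactual NDVI, never through
residual offsets. Predictions are clipped to `[0, season_length]` days
(clipping is logged); population, water and `d_w` are never modified.

- *Uniform*: every land pixel with observed NDVI below the 0.85 cap gains
  `δ`, capped at 0.85.
- *Targeted*: the target set is the minimal descending-population prefix
  reaching an 80% population share (ties by pixel id). The matching
  increment is solved by bisection on `[0, cap]` to relative tolerance
  1e-6; predicted exposure is monotone non-increasing in the increment
  (the spatial multiplier `(I − ρW)⁻¹` has non-negative entries for
  `0 ≤ ρ < 1`), so the root is unique up to cap-saturated flats and the
  smallest root is returned. A target unreachable even at the full cap
  returns an explicit infeasibility record with the best achievable
  reduction — not an exception and not silent NA.

The savings statistic `100·(NDVI₈₀ − NDVI_all)/NDVI_all` is computed
exactly as printed, on city-wide NDVI sums after each intervention; it is
negative when targeting adds less vegetation, and summaries report the
magnitude alongside — no sign convention beyond that is asserted. The
sweep tabulates, per global `δ`, the uniform reduction, the solved local
increment, the savings and the local-minus-global difference.

## The synthetic generator

The generator produces the statistical structure the analysis assumes,
not a physical city:

- *Population*: monocentric exponential surface (default e-folding
  5 km, 10⁶ residents), integerized by largest-remainder so the total is
  conserved exactly; zero on water.
- *NDVI*: Gaussian random field (white noise smoothed by FFT
  convolution, standardized; default correlation length 5 km) min-max
  rescaled into a configured range. The exact covariance family is not
  load-bearing — only smoothness and seedability are.
- *Water*: a one-cell edge strip by default (a river-front), a disc, or
  absent (which exercises the `dw_excluded` path).
- *Counts*: drawn directly from the spatial lag process on the land
  pixels, `(I − ρW)y = Xβ + ε`, by sparse solve, then clipped to
  `[0, season_length]` (clipping is logged; heavy clipping would
  invalidate recovery checks, and the default regime produces none).
  Defaults: day β = (10, −4.7, −1.2), night β = (10, −2.7, −0.6) — the
  fold-averaged magnitudes the model family recovers on real multi-city
  data — with ρ = 0.5 and σ = 0.5 days as repository simulation defaults
  (the spatial parameter and noise scale are not externally reported
  values).
- *LST series* (optional): back-filled so the exposure stack reproduces
  the generated counts. Per pixel and year an integer number of hot days
  is placed, hot and cool values separated by a wide gap; the reporting
  percentile at which the pooled threshold falls inside the gap is
  stored with the series. A fixed percentile (say 90) cannot reproduce
  arbitrary counts — the pooled threshold cuts a fixed fraction of the
  distribution — so the series carries its own consistent percentile
  instead. This is a construction for exercising the exposure code, not
  an LST simulation.

What the generator does **not** emulate: satellite retrieval gaps and
view-angle effects, non-Gaussian LST tails, polycentric or irregular
urban forms, population–vegetation correlation, coastline geometry.
Passing tests therefore demonstrate correctness of the estimators and
engines under the assumed process, and calibration of the recovery
pipeline — not fidelity of any specific real city.

## Problem sizes and numerical checks

The test suite runs cities between 5×5 and 40×40 cells; coefficient
recovery uses 25 replicate 40×40 cities (~1560 land pixels each) for each
of the day and night coefficient pairs, which one CPU completes in about
a minute per pair. Oracle equivalences pin the fast paths to brute force:
the distance transform against exhaustive nearest-water search (≤ 30×30
masks, 1e-9 m), k-NN weights against full pairwise sorts, the
concentrated-likelihood maximum against a dense grid search over ρ in
steps of 0.01 (β to 1e-8 at matched ρ), and reduced-form prediction
against dense matrix inversion (1e-10).

Scenario demonstrations use a sparsely vegetated monocentric city (NDVI
rescaled to [0.05, 0.35]): with observed greenness well below the 0.85
cap, increments up to 0.5 almost never truncate, which is the regime in
which exposure responds near-linearly to greening and the uniform and
targeted scenarios are cleanly comparable. Recovery simulations keep the
wider [0.1, 0.8] NDVI range.

## Known limitations

Surface temperature is not air temperature or thermal comfort; exposure
in person·days weights every resident equally and ignores indoor
conditions, humidity, wind and vulnerability. Scenario increments ignore
space availability, cost and equity constraints. The model is linear in
its two surface predictors — albedo, building morphology and
anthropogenic heat are absorbed by the intercept, the spatial term and
the noise. Coefficients fitted to one city transfer to another only to
the extent the cities share their surface-climate coupling.
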