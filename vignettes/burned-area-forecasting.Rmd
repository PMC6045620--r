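---
title: "Empirical seasonal burned-area forecasting from drought indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical seasonal burned-area forecasting from drought indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firecast)
```

## The model

In many fire-prone regions the year-to-year variability of seasonal burned
area (BA) is driven to a large degree by antecedent and concurrent moisture
conditions: abundant-fuel ecosystems burn more after drought, while arid,
fuel-limited ecosystems burn more after anomalously wet spells that build
fuel. `firecast` implements an intentionally minimal empirical model that
captures this with a single standardized drought index per grid cell:

$$\mathrm{BA} = \beta \, \mathrm{SPI}_t(M - m) + \varepsilon$$

where both sides are detrended, standardized seasonal anomalies. `SPI_t` is
the standardized precipitation index accumulated over `t` months, `M` is
the last calendar month of the target season (February, May, August or
November), `m` is the lag of the index's target month back from `M`, and
`beta` is the sensitivity of BA to dry/wet conditions in standardized
units. The candidate set is deliberately small and fixed: `t` in {3, 6, 12}
months and `m` in {0, ..., 5}, i.e. 18 candidate predictors per cell and
season, spanning concurrent to half-year-antecedent moisture on seasonal to
annual accumulation scales.

Per cell, the best candidate is chosen by (i) fitting each candidate under
leave-one-out cross-validation (LOOCV), (ii) testing the Pearson
correlation between cross-validated predictions and observations with a
one-tailed test (a useful forecast must correlate *positively*; the sign
of `beta` itself is free), and (iii) keeping the maximum-correlation
candidate among those with p < 0.05. Cells with no significant candidate
are left unmodelled. No multiple-testing correction is applied across the
18 candidates or across cells; the consequence is quantified below.

All trend and regression fits use iteratively reweighted least squares
with a Tukey bisquare weight function (tuning constant 4.685, the
conventional 95%-Gaussian-efficiency choice; tolerance 1e-8, at most 50
iterations, ordinary least squares as the fallback on the rare
non-convergent series, about 0.5% of pure-noise draws). Robustness matters
because seasonal BA series contain occasional extreme fire years that
would otherwise dominate a 21-point least-squares fit.

### Leakage discipline

Every quantity entering a prediction for year *y* is computed without year
*y*: the BA and predictor trends, their standardizing means and standard
deviations, the regression coefficients, and (on the forecast side) the
bias-correction scaling factors. Observed indicator values themselves are
rank-standardized on the full observational record - observations of the
*predictor* are legitimately available in an operational setting; it is
the *predictand*'s year that must not leak. For forecast-driven
predictors, the predicted year's observed accumulation is replaced by the
merged observation+forecast value before ranking, so it never enters its
own standardization.

## Indices

SPI follows the nonparametric route: `t`-month rolling accumulation, then
per calendar month a rank-based transform through Gringorten plotting
positions `(i - 0.44)/(n + 0.12)` and the inverse normal CDF. Ties
(including runs of zero precipitation) get average ranks; an all-tied
sample maps to zero. The Gringorten position is the standard choice in the
nonparametric standardized-index literature because it is bounded away
from 0 and 1 (Weibull `i/(n+1)` is available as an option). With `n`
values per calendar month the resulting sample is a fixed set of normal
quantiles, so the per-month mean is ~0 and the standard deviation
approaches 1 from below as `n` grows (0.999 at `n` = 833, 0.95 at
`n` = 21) - the small-sample shrinkage is a property of any
plotting-position standardization, not an implementation artifact.

SPEI applies the same transform to the climatic water balance `P - PET`
with Thornthwaite monthly potential evapotranspiration (temperature and
day-length based; PET = 0 at or below 0 degC). The temperature indicator is
different by construction: a `t`-month running mean standardized by
moment-based z-scores per calendar month, not by ranks.

## Preprocessing

All inputs live on regular lat-lon grids. Burned area, an extensive
quantity, is coarsened by exact block sums (missing fine cells count as
zero, with a missing-fraction diagnostic); temperature is interpolated
bilinearly; precipitation uses first-order conservative (overlap-area
weighted) remapping, with spherical band areas in latitude. Cells are only
modelled where seasonal BA is nonzero in more than half of the available
years (at least `floor(n/2) + 1` of `n`; 11 of 21 in the standard
record) - elsewhere a 21-point regression on a mostly-zero series would be
meaningless. Seasons are DJF/MAM/JJA/SON with DJF labelled by the year of
January/February.

## Forecast side

A seasonal forecast archive holds, for one issue date per year (one month
before the season starts: May issues for JJA), monthly fields at leads
0..L. Bias correction is per cell, lead and calendar month: precipitation
is scaled by the ratio of observed to forecast long-term means,
temperature shifted by their difference, always excluding the forecasted
year (leave-one-out). Ratios against near-zero dry-cell climatologies are
capped to [0.2, 5] and logged. To build a predictor for year *y*, months
strictly before the issue date come from observations and later months
from the corrected forecast; candidates whose accumulation window closes
before the issue date need no dynamical forecast at all - one reason the
long-accumulation, long-lag candidates retain skill even from poor
forecast systems. Multi-model ensembles average the corrected fields; the
"best-k" ensemble ranks systems by the fraction of eligible area with a
significant BA model.

## The synthetic world

Because the real satellite/reanalysis/hindcast archives are external, the
package ships a generator that produces worlds with the exact statistical
structure the model assumes, plus known ground truth: gamma monthly
precipitation with a seasonal cycle (default shape 2, scale with annual
cycle around 50 mm/month), AR(1) temperature anomalies on a seasonal
cycle, BA built as `beta_true * SPI_{t_true}(lag_true) + noise` mapped
affinely to hectares (baseline 1000 ha, 250 ha per standardized unit,
floored at 0), with optional linear trends and zero inflation, and
pseudo-forecast systems whose anomaly is `alpha` times the observed
anomaly plus `sqrt(1 - alpha^2)` independent noise per lead, with
configurable multiplicative/additive biases. Defaults mirror the standard
study conditions: 21 season-years (plus 2 lead-in years so every candidate
window is covered), `beta_true = -0.8`, `t_true = 6`, `lag_true = 1`,
noise sd 0.3.

What the generator does *not* emulate: spatial covariance between cells
(cells are independent, which makes them ideal for counting experiments
and wrong for field-significance questions), heavy-tailed BA noise
(Gaussian by default), fuel/vegetation dynamics, and sub-monthly weather.
Passing recovery tests on this world demonstrates the statistical
machinery is correct, not that real burned area is this predictable.

## A worked example

```{r example, eval = FALSE}
library(firecast)

sc <- synthetic_scenario(n_lat = 5, n_lon = 5, seed = 7)
cl <- generate_climate(sc)
ba <- generate_ba(sc, cl$precip, season_spec("JJA"))

cubes <- lapply(c(3L, 6L, 12L), function(t) compute_spi(cl$precip, t))
names(cubes) <- c("3", "6", "12")
mask <- burnable_mask(ba)
fits <- fit_fire_model_grid(ba, cubes, mask = mask)
skill_summary(fits)
beta_sign_fraction(fits)

spec <- pseudo_forecast_spec("sys1", alpha = 0.7, precip_bias = 1.2,
                             seed = 11)
arc <- generate_forecast_system(spec, cl$precip, cl$temp, sc$ba_years)
arc <- bias_correct(arc, cl$precip, cl$temp)
fc_fits <- fit_fire_model_forecast(ba, cl$precip, arc, mask = mask)
skill_summary(fc_fits)
```

## Numerical and design choices

* **IRLS details.** Scale is re-estimated each iteration as
  `median(|r|)/0.6745`; a zero scale (perfect fit) terminates immediately
  with the exact least-squares solution; total weight collapse or
  non-convergence falls back to ordinary least squares. Inside the LOOCV
  kernel the fallback is silent; the user-facing `robust_detrend()` warns.
* **One-tailed test.** `H1: r > 0` on cross-validated predictions, t
  transform with `n - 2` degrees of freedom. Under the null the LOOCV
  correlation is not exactly t-distributed; the measured single-candidate
  rejection rate at nominal 5% is about 5.7% for `n = 21`.
* **Selection inflation.** Maximizing `r` over 18 (correlated) candidates
  with only a per-candidate 5% test marks about 33% of pure-noise cells as
  significant (`null_selection_rate`, measured once on 10,000 null cells).
  Significant-area fractions must be read against this base rate, which is
  why the package exports it.
* **Tie-breaking.** Equal `r` resolves to the smaller `t`, then the
  smaller lag - parsimony and recency, and determinism above all.
* **Null model.** The leave-one-out climatology prediction of a
  standardized series is `-z_y/(n-1)`, an affine *decreasing* function of
  the held-out value, so its correlation with observations is exactly -1;
  this degeneracy is inherent to the literal construction and documented in
  `null_model_climatology()`, which also offers the flat full-period-mean
  alternative.
* **Bootstrap for correlation differences.** Fitted-vs-null comparisons
  resample whole years with replacement and recompute both correlations on
  the shared resample (the two correlations are dependent, so closed-form
  independence tests do not apply); 1000 replicates and a two-sided 95%
  interval by default, seeded for reproducibility.
* **Problem sizes.** The recovery and ordering experiments in the test
  suite use 500-cell worlds (25 x 20) and 21 years, which keeps every
  experiment's runtime modest while leaving binomial noise on counted
  fractions near or below one percentage point; the null-rate measurement
  pools 10,000 cells.

## Known limitations

Single-predictor linearity (a two-predictor SPI + temperature variant is
provided, but no nonlinear or multi-factor models); no human, land-use or
fuel covariates; the 18-candidate search is not corrected for multiple
testing, mirroring the modelling tradition it follows, so per-cell
significance is optimistic; independent-cell synthetic worlds cannot
validate spatial field significance; and the forecast side assumes one
issue date per year at one month of lead.
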