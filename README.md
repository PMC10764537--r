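# mfac — Modified Flow Accumulation Capacity modelling for blanket bogs

`mfac` predicts the relative surface wetness of blanket peatlands from
bare-earth LiDAR terrain models, and links those predictions to measured
water-table behaviour. It is aimed at peatland ecohydrologists and
restoration planners who need to rank areas of a bog by their capacity to
sustain shallow, stable water tables — the precondition for peat-forming
vegetation — using topographic data alone.

## The model

The core quantity is the **Modified Flow Accumulation Capacity**, a
topographic-wetness-index variant adapted to rain-fed peatlands:

```
MFAC = (sqrt(A) / s) * K        [km]
```

where per 1 m grid cell

* `A` — upstream contributing catchment area (m²), from D8 flow routing on
  the sink-filled DTM, sampled every 5 m along extracted flowlines and
  spread across the catchment by Sibson natural-neighbour interpolation;
* `s` — local surface slope (m km⁻¹), from Horn's method on a 5 m
  focal-mean smoothed DTM (the smoothing removes hummock/hollow
  microtopography that would otherwise swamp the slope signal);
* `K` — a dimensionless climatic correction, the site's long-term annual
  effective rainfall (precipitation − potential evapotranspiration)
  divided by a 907 mm/yr reference, which makes MFAC comparable between
  sites spanning a rainfall gradient.

Cells whose contributing area exceeds a site-specific stream-formation
threshold are masked out: once a defined channel forms, accumulating area
drains rather than wets the surface.

High MFAC marks flat, persistently fed ground (shallow, stable water
tables); low MFAC marks steep or weakly fed ground (deeper, flashier
water tables). The package quantifies that relationship as an OLS
regression of summer water-table exceedance statistics (D90, the level
exceeded 90 % of the time; D1 − D99, the fluctuation range) on
log₁₀(MFAC), with ANOVA F tests and prediction intervals.

Alongside the terrain pipeline there are tools for hourly logger series
(seasonal subsetting, duration-curve percentiles), daily meteorological
summaries (rain days ≥ 1 mm, wet days ≥ 5 mm, seasonal proportions),
hydraulic gradients from triangular well nests, synthetic generators
(terrain, met forcing, water-table series) and transcriptions of the
summary tables from a four-site Irish monitoring campaign (Garron,
Cuilcagh, Letterunshin, Fiddandarry) so that every stage runs
self-contained.

## Worked example

Regress the bundled per-well summer D90 statistics on log₁₀(MFAC) and
inspect the fit:

```r
library(mfac)

t3  <- load_study_table("well_stats")   # 37 wells across four bogs
fit <- fit_log_linear(t3$mfac_km, t3$d90_2019_m, t3$well_id)
fit
#> OLS: response = -0.2469 +0.1719 * log10(MFAC km)
#> n = 35, r2 = 0.624, F(1, 33) = 54.74, p = 1.69e-08
```

So in summer 2019 a ten-fold increase in MFAC raises the D90 water table
by about 17 cm, and MFAC alone explains 62 % of the between-well variance.
The fitted line evaluated at the wetness-class edges recovers the class
scheme's predicted D90 bands (≈ 30, 25, 20 and 13 cm below ground at 0.5,
1, 2 and 5 km):

```r
class_boundaries_from_fit(fit)
#>   mfac_km predicted_d90_cm
#> 1     0.5         29.86596
#> 2     1.0         24.69159
#> 3     2.0         19.51723
#> 4     5.0         12.67709
```

Run the full terrain pipeline on a synthetic bog and map its wetness
classes:

```r
res <- run_site(synthetic_site_config(), quiet = TRUE)
res$distribution
#>   label   percent
#> 1 0-0.5 37.016644
#> 2 0.5-1 32.561632
#> 3   1-2 28.019021
#> 4   2-5  2.077337
#> 5    >5  0.325366
```

`res$paths` lists the written artifacts: the MFAC and class grids (ESRI
ASCII), flowlines (GeoJSON), the class-distribution CSV and a run
manifest with config and output hashes. A thin command-line wrapper with
`dem`, `wt-stats`, `met`, `regress`, `simulate` and `reproduce`
subcommands is installed at `system.file("cli/mfac.R", package = "mfac")`.

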