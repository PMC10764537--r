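---
title: "MFAC modelling of blanket-bog surface wetness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MFAC modelling of blanket-bog surface wetness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

Blanket bogs are rain-fed peatlands that mantle undulating terrain, so
their wetness is organised by topography: flat ground and ground fed by a
persistent upslope catchment stays wet through dry spells, steep or
weakly fed ground dries out. The Modified Flow Accumulation Capacity
condenses this into one number per cell,

$$\mathrm{MFAC} = \frac{\sqrt{A}}{s}\,K \quad [\mathrm{km}],$$

with $A$ the contributing catchment area (m²), $s$ the local slope
(m km⁻¹) and $K$ a climatic scaling — the site's annual effective
rainfall (precipitation minus potential evapotranspiration) over a
907 mm yr⁻¹ reference, so a site with $K=1.32$ receives 32 % more
effective rainfall than the reference bog and the same terrain is
correspondingly wetter.

The model assumes hydrological behaviour is dominated by surface and
near-surface flow through the acrotelm, and that losses to the substrate
beneath the peat are negligible. Both assumptions hold on intact blanket
bog but fail in two known ways: (i) where a defined stream channel forms,
additional contributing area *drains* the peat instead of wetting it —
handled by masking cells above a site-specific stream-formation
threshold; (ii) where subsurface macropores or peat pipes discharge water
with no topographic expression — not detectable from a DTM at all, and
the reason predicted-minus-observed residual maps are part of the
package's output: a well that is much drier than its MFAC predicts is a
flag for drains or piping, not noise.

## Pipeline stages and numerical choices

**Depression filling.** `fill_sinks()` is a priority-flood fill with an
epsilon gradient of $10^{-5}$ m per cell step. The epsilon resolves flats
deterministically (every cell keeps a strictly descending path to an
outlet), makes the operation idempotent, and is far below the ±0.15 m
vertical accuracy of the source LiDAR, so it never affects mapped values.
Valid cells on the grid edge or bordering nodata are the drainage seeds.

**Flow routing.** `d8_flow_direction()` sends each cell to the steepest
downslope neighbour (drop over distance, diagonals $\sqrt 2$ longer).
Exact ties are broken by the fixed neighbour order E, SE, S, SW, W, NW,
N, NE — first maximum wins — so results are bit-reproducible across
platforms. Routing runs on the *raw* filled 1 m DTM; the smoothed DTM is
used only for slope. Smoothing before routing would move channels
sideways; microtopography barely affects which way water leaves a cell
but badly corrupts slope estimates, hence the split.

**Accumulation.** `flow_accumulation()` is self-inclusive: a cell counts
its own area, so the minimum is one cell area. MFAC takes $\sqrt A$, and
an upstream-only convention would make every ridge cell degenerate at
$A=0$. Comparisons against GIS outputs using the upstream-only convention
need one cell area added.

**Slope.** Horn's 3×3 finite differences on the 5 m focal-mean smoothed
DTM, expressed in m km⁻¹. The 5 m window (rather than the 20 m used for
raised bogs, whose relief is gentler) is implemented as a focal mean on
the 1 m grid, *not* a resample to 5 m cells, so the slope field keeps 1 m
support; `resample_block_mean()` exists for sensitivity tests of the
alternative reading. Slopes are floored at `s_min` (package default
0.1 m km⁻¹) to keep $\sqrt A / s$ finite on perfectly flat cells; the
floor is configurable per site and the synthetic-site configuration uses
2 m km⁻¹ (see below). Edge cells use replicated border values; missing
neighbours fall back to the centre value.

**Flowlines and area sampling.** Cells with $A$ at or above
`flowline_threshold_m2` form the flowline network; the network is walked
into maximal chains that split at confluences, and contributing area is
read off every 5 m of arc length, each point carrying its host cell's
$A$ (the value is a step function along the line; interpolating between
cells would manufacture areas no cell drains). The threshold is not a
quantity the campaign reported; the default is 0.1 ha (1000 m²), exposed
in the configuration, and results are insensitive to it in the tested
range because interpolation is anchored by the sampled values, not by
where sampling starts.

**Natural-neighbour interpolation.** `sibson_interpolate()` implements
exact-geometry Sibson interpolation: the weight of sample $s$ for query
$q$ is the area the Voronoi cell of $q$ (in the diagram augmented with
$q$) steals from the original cell of $s$, computed by half-plane
clipping of convex polygons with a nearest-first pruning rule. The
estimate is exact at sample locations and has linear precision in the
interior, both enforced by tests at $10^{-6}$ relative error. Sibson
weights are undefined outside the convex hull of the samples; such cells
take the nearest sample's value, a documented extrapolation rule that
affects only the catchment fringe beyond the outermost flowlines. Fewer
than three non-collinear samples trigger a nearest-sample fallback with a
warning. Raw accumulation, not its logarithm, is interpolated; the
class boundaries below 2 km would be distorted by back-transforming a
log-space average.

**Stream masking.** Applied twice: sample points at or above the
stream threshold are excluded *before* interpolation (channel values must
not inflate the wetness surface), and output cells whose raw or
interpolated $A$ reaches the threshold are masked (channels receive no
MFAC). The thresholds are empirical per site — 2.0, 1.5, 5.0 and 5.0 ha
for the four bundled sites — because where a channel first forms depends
on climate and terrain.

**Classification.** Five left-closed bins — [0, 0.5), [0.5, 1), [1, 2),
[2, 5), [5, ∞) km — each mapped to the summer D90 band the pooled 2019
regression predicts at its edges (≥ 30, 25–30, 20–25, 13–20, < 13 cm
below ground). A cell at exactly 2.0 km belongs to the wetter 2–5 class.

## Water-table and meteorological statistics

Exceedance statistics come from the duration-curve convention: D90, the
level equalled or exceeded (i.e. at least as shallow) 90 % of the time,
is the 10th percentile of hourly levels; D10 the 90th; the fluctuation
range is D1 − D99. Quantiles use the linear-interpolation (type 7)
convention; the convention is not dictated by the campaign's reports, and
at 2 dp a different choice can shift D90 by a centimetre on short
records, so it is fixed and documented here. Summers are April–September
of one calendar year, winters January–March plus October–December.
Records with gaps are summarised over the available hours without
imputation; series shorter than `min_obs` (default 100 observations) are
refused rather than summarised. Seasons that were not monitored simply
drop out well-by-well (listwise per season), which is what reproduces the
published degrees of freedom (35 wells in 2019, 33 in 2020, 68 pooled).

Meteorological summaries count rain days (≥ 1 mm) and wet days (≥ 5 mm)
inclusively and report seasonal proportions rounded to integer percent,
matching the tabulated display convention. Horizontal hydraulic gradients
are the gradient magnitude of the plane through a well triad's three
heads; vertical gradients are (shallow − deep)/separation, positive
downwards.

## Regression analysis

`fit_log_linear()` regresses a signed level (m relative to ground,
negative below) on log₁₀(MFAC) by OLS and reports r², the ANOVA F on
(1, n−2) degrees of freedom and its p value. Base 10 is a display choice;
r², F and p are base-invariant and the slope rescales by ln 10.
Confidence and prediction intervals use the t distribution on n−2 df.
No multiple-testing correction is applied: each regression is reported
with its own ANOVA p, as in the source campaign.

One convention deserves note. The bundled well table prints levels at
2 dp, so a well whose tabulated D90 is exactly −0.20 m cannot be
distinguished from one marginally deeper. `threshold_counts()` therefore
counts levels tied with the cut as exceeding it by default
(`ties = "deeper"`); the strict variant is available. With the default,
the bundled 2019 table yields 13 wells under 1.5 km MFAC of which 11 are
more than 20 cm below ground — the published count.

## The synthetic data generators

The generators exist so that every pipeline stage can be exercised, and
its statistical contracts tested, without distributing LiDAR tiles or
logger archives. They are phenomenological; each has one structural
contract and no pretence of physics.

**Terrain** (`generate_bog_dem()`): a regional tilt draining east
(default 20 m km⁻¹, i.e. 2 %, at the gentle end of the relief of real
blanket-bog catchments), one or more plateaus with linear aprons, an
optional incised channel and carved drains (0.5–0.75 m deep is the
typical historical ditch), plus Gaussian cell noise. Plateau tops are
weakly domed (default 6 m km⁻¹ = 0.6 %, the slope of the flattest real
well nest) because a perfectly flat disc is both unreal and degenerate
under the slope floor. The noise default (2 cm sd) models the residual
fine-scale roughness that survives 5 m smoothing, not raw hummock relief,
which smoothing is designed to remove. All structure is deterministic
given the seed.

**Met forcing** (`generate_met_series()`): daily precipitation with
winter-weighted occurrence and intensity, normalised exactly to the
requested annual total; daily PE from a summer-peaked seasonal shape with
mild lognormal noise, normalised likewise. The shape constants were set
once so that the April–September PE share sits near the observed 80 %
(test band 0.75–0.85 across seeds) and annual rain-day counts land near
the observed ~200.

**Water tables** (`generate_water_table_series()`): a linear-reservoir
bucket at hourly resolution — recharge from daily rain, recession rate
decreasing in log₁₀(MFAC) to mimic the drawdown resilience of
well-fed ground — whose deterministic component is anchored so that its
summer 10th percentile equals $a + b\log_{10}(\mathrm{MFAC})$ plus a
per-well noise draw, then capped at a small overtopping bound (+0.05 m).
The anchoring makes the simulator's contract exact: the simulated summer
D90 of a well is the regression model plus N(0, σ²) noise, which is what
lets the recovery test demand nominal CI coverage. Defaults a = −0.35 m,
b = 0.12 m per decade, σ = 0.04 m. Note that *joint* coverage of two
nearly uncorrelated 95 % confidence intervals is about 0.95² ≈ 90 %, so
a recovery rate slightly either side of 90 % over 50 replicates is the
expected behaviour of a correct simulator, not a defect.

What passing tests on synthetic data do **not** show: the generators
contain no peat pipes, no functional drains interacting with the water
table, no losses to depth, and no spatial correlation of water-table
noise — precisely the processes that produced the outliers in the real
campaign. Synthetic results validate the machinery and its statistical
behaviour under the model's assumptions, not the model's adequacy on a
damaged bog.

**The synthetic site configuration** (`synthetic_site_config()`) scales
the pipeline thresholds to the ~0.5 ha default terrain: streams form at
0.1 ha, flowlines seed at 150 m², and the slope floor is 2 m km⁻¹
(slopes below that on a 5 m-smoothed surface are beneath the LiDAR noise
floor). Climate is Letterunshin-like (907 mm yr⁻¹ effective rainfall, so
K = 1). Under this configuration the end-to-end MFAC surface stays inside
the plausible 0–15 km band across seeds.

## Problem sizes used by the test-suite

Brute-force routing oracles run on fifty 10 × 10 grids; the interpolation
and regression oracles use dozens of points; pipeline determinism and
scaling checks use a 40 × 50 cell site; simulator recovery uses 50
replicates of 40 wells with one year of hourly data each. These sizes
keep every oracle literal (path tracing from every cell, quantiles from
sorted arrays, OLS from the normal equations) while the full suite runs
in well under a minute.

## Known limitations

* D8 single-direction routing only; no D-infinity or multiple-flow
  partitioning, and filling is the only depression treatment (no
  breaching).
* Planar metric coordinates are assumed; there is no reprojection.
* GIS raster exchange is ESRI ASCII (the format the source DTMs were
  delivered in) plus GeoJSON for flowlines.
* The ecological survey side of the campaign is represented only by its
  residual table; the package fits no vegetation models.
* Sibson extrapolation beyond the sample hull is nearest-sample by
  definition here; fringe cells outside the outermost flowlines carry
  that approximation.
* Smoothing is applied before any site-boundary clipping (smooth-then-
  clip); if a mask is supplied, cells outside it are dropped after the
  smoothed slope is computed, so boundary slopes use the full terrain
  context.
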