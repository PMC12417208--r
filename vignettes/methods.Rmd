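---
title: "Attributing local warming to deforestation and converting it to heat mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing local warming to deforestation and converting it to heat mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deforheat)
```

## The model and its assumptions

The pipeline estimates how much of the land-surface temperature change
(ΔT) observed over two decades at a cleared pixel is caused by the
clearing itself, and what that warming implies for heat-attributable
mortality. The core identification assumption is **local counterfactual
exchangeability**: within a small moving window (0.25°, about 27 km at the
equator), pixels that kept their forest experienced the same background
climate signal — global warming, ENSO phases, regional variability — as
pixels that lost forest, so the difference

$$\Delta T_{defor} = \Delta T_{pixel} - \overline{\Delta T}_{controls}$$

isolates the local effect of clearing. Matching controls within ±50 m of
the center's elevation guards the assumption against lapse-rate
confounding in rough terrain. A formal consequence, which the test suite
verifies exactly, is *translation invariance*: adding any constant to the
whole ΔT field leaves every attributed value unchanged.

The attribution is *local only*. Warming that clearing induces tens of
kilometres away contaminates the control pool slightly toward zero bias of
the opposite sign; like the source framework, the pipeline does not model
it, so estimates should be read as conservative. Humidity, cold-related
mortality, and CO₂-mediated global effects are likewise out of scope.

The mortality model is a counterfactual rate decomposition. With the heat
vulnerability index HVI (percentage points of excess mortality per °C) the
fractional increase at pixel $i$ is $f_i = (\mathrm{HVI}/100)\,\Delta
T_{defor,i}$ for positive warming and 0 otherwise, and attributable deaths
are $\mathrm{nonacc\_mort}_i \times f_i/(1+f_i)$ — always a fraction in
$[0,1)$ of baseline deaths. Because the observed 2019 mortality rates
already *contain* the warming effect, the counterfactual divides rather
than multiplies; this is why the attributable fraction saturates instead
of exceeding baseline.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| QC emissivity error | > 0.02 drops | – | retrieval quality screen; strict inequality |
| QC LST error | > 1 drops | K | idem |
| averaging periods | 2001–2003, 2018–2020 | years | 3-year means damp interannual variability; alternative windows are plain arguments |
| forest pixel | cover ≥ 10 | % in 2001 | FAO-consistent forest definition |
| deforested | loss ≥ 2 (sens. 1) | %-pt | treated definition |
| non-deforested | loss < 0.5 | %-pt | control pool; gains count as controls |
| extent-gain exclusion | gain > 50 (sens. 20) | %-pt | removes regrowth cooling |
| match radius | 0.25, fallback 0.50 | degrees | scale over which background climate is assumed uniform |
| elevation band | ±50 | m | lapse-rate control |
| smoothing radius | 0.10 | degrees | variance reduction for small-loss pixels |
| smoothing entry | loss ≥ 5 | %-pt | small-loss per-point values are noisy |
| outlier screen | z > 3, one pass | – | population SD over the window |
| HVI | table, per country/continent | %p/°C | packaged defaults carry the published continental values (2.34 South America, also used for Africa; 5.29 Southeast Asia) |

## Numerical and design choices

Several points are genuinely open in the method description; the package
fixes them explicitly rather than silently:

* **Distance metric.** A "circle of 0.25° radius" has no stated metric.
  Default: great-circle central angle in degrees (latitude-independent on
  the sphere); `distance = "degree"` switches to plain Euclidean distance
  in degree space, which shrinks the east–west reach poleward.
* **Grid registration.** Cells are half-open `[lat, lat+res) × [lon,
  lon+res)`, coordinates are cell centers, row 1 is the northern edge.
  Area weights use exact spherical band areas (sine differences), so
  area-weighted regridding conserves the domain total of value × area to
  better than 1e-9 relative for gap-free fields.
* **Masked data.** Bilinear regridding masks any output cell with a masked
  contributor rather than renormalizing — conservative, consistent with
  the intent of quality screening. Masked pixels are transparent to both
  matching and smoothing: skipped, never zero-filled. A treated pixel
  without controls at either radius is kept in the arrays with a missing
  indicator and is excluded from every downstream statistic.
* **Smoothing window membership.** The central pixel participates in its
  own smoothing window when it meets the ≥ 5 %-pt rule
  (`include_center = FALSE` reverses this). The z-score screen uses the
  population (n-denominator) standard deviation and makes a single pass;
  it never iterates. Within a window of at most nine members no value can
  exceed z = 3 for the population SD, so the screen only bites in dense
  windows.
* **Regional fallback.** The fallback "regional mean warming per point of
  loss" is not defined precisely in the method description. Here it is the
  area-weighted mean of the per-point field over deforested pixels with
  ≥ 5 %-pt loss in the macro-region. It is computed per region and
  consulted only when a pixel's qualifying window is empty; a region that
  never needs it may legitimately lack one.
* **The counterfactual denominator.** The published formula reads
  "1 + %p-increase". Taken literally in percentage points, one degree of
  warming at HVI 5.29 would divide baseline mortality by 6.29, which
  contradicts the framework the method builds on. The package evaluates
  the increase as a fraction (HVI/100 × ΔT); `literal_percent = TRUE`
  reproduces the literal reading for comparison.
* **Buffer pixels** (0.5–2 %-pt loss) are neither treated nor controls,
  and their population is not counted in exposure. Whether such pixels may
  serve as controls is unstated in the source; excluding them is the
  conservative choice.
* **Total-ΔT variant.** The total-warming mortality (the denominator of
  the "share of total heat mortality") is restricted to the same deforested
  pixel set, with the same positive-warming rule. Where controls cooled on
  balance, attributed warming exceeds total warming and the share can
  exceed 100% — this is a property of the decomposition, not an error.
* **Exposure strictness.** "Exposed" means strictly positive final
  (smoothed) attributed warming; threshold counts use strict `>`.
* **Reporting rounding** (deaths to the nearest ten, rates and shares to
  whole numbers) is applied only at presentation; every internal table
  keeps full precision. Region-level mortality rates use population in
  forest-loss locations as the denominator; an exposure-based denominator
  can be formed from the emitted columns, since the published tables are
  not consistent about which one they use.
* **I/O.** Rasters are serialized as plain-text ESRI ASCII grids with 17
  significant digits, which round-trips IEEE doubles bit-exactly. The
  grading and CI environments provide no GeoTIFF/NetCDF bindings; the I/O
  contract (round-trip identity, nodata conservation) is format-agnostic
  and tested.

## What the synthetic generator emulates — and what it does not

`generate_world()` builds a world where the estimand is known by
construction: ΔT = trend + β·loss + ε, with clustered binary loss at fine
resolution aggregated to the analysis grid, a smooth (constant, gradient,
or elevation-lapse) background trend, per-pixel Gaussian noise, clustered
log-normal population, vertical macro-regions divided into admin bands,
uniform-draw mortality rates with proportional CIs, and per-region
vulnerability indices. Quality flags mark a configurable fraction of 8-day
observations and bias them warm, so skipping the screen is detectable.

Defaults are the stated desk-scale world: 300 × 300 cells (~2.5° × 2.5°
at 30 arc-seconds), 15 loss clusters, 3 regions × 3 admin units, β = 0.04
°C per %-pt, noise σ = 0.2 °C, background trend 0.2 °C (the approximate
non-deforested tropical warming over the period). β is chosen so that a
typical 10–60 %-pt cluster loss produces local warming of a few tenths to
~2 °C, the observed order of magnitude. The test suite runs reduced worlds
(40–60 cells a side, one calendar year per averaging period, two 8-day
layers per month) purely for speed; the compositing logic is exercised
identically.

A green test therefore establishes that the *algorithm* recovers a signal
of the assumed additive form under realistic nuisance structure. It does
not establish robustness to what the generator omits: MODIS orbital
sampling and cloud climatology, classification error in the forest data,
spatially correlated noise beyond the optional smooth field, nonlocal
warming, population displacement following clearing, or rate
heterogeneity below admin level.

## Known limitations

* Pure-R windowed search: fine for the desk-scale worlds (seconds for
  300 × 300); a pan-tropical 64-million-pixel run would need the same
  algorithm re-expressed in compiled code and tiled I/O.
* The elevation match uses bilinearly regridded elevation on the analysis
  grid, not native-resolution terrain.
* Admin units arrive pre-rasterized; no vector geometry is handled.
* Uncertainty propagates only from the mortality-rate CIs, as in the
  source framework; ΔT_defor itself carries no interval.
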