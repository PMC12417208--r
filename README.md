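# deforheat

Tropical deforestation warms the cleared land itself: removing canopy
lowers evapotranspiration and raises daytime land surface temperature (LST)
by amounts comparable to decades of global warming. For the people who live
on and around cleared land this is a health exposure, because excess
mortality rises with temperature. `deforheat` implements, as a tested and
reusable R pipeline, the analysis chain that isolates this *local,
deforestation-induced* warming from two decades of gridded temperature
change and converts it into population exposure and an annual
heat-attributable non-accidental mortality burden. It is aimed at
environmental-health and land-use researchers who want to run, probe, or
extend this attribution chain on their own gridded inputs — or on fully
synthetic landscapes with known ground truth.

## The method

All fields live on a regular latitude/longitude grid (nominally 30
arc-seconds across the tropics, 25°S–25°N).

1. **Temperature change.** 8-day LST composites are quality-screened
   (emissivity error > 0.02 or LST error > 1 K are dropped, strictly),
   composited to months ignoring missing periods, averaged over two 3-year
   periods (2001–2003 and 2018–2020 by default), bilinearly regridded, and
   differenced: ΔT = end-period mean − start-period mean.
2. **Forest change.** Year-2000 canopy cover is subjected to annual loss at
   fine resolution, aggregated by area-weighted regridding, and differenced
   (2020 − 2001, percentage points). Cells with > 50 %-pt net forest-extent
   *increase* are excluded (regrowth cooling would contaminate the signal).
   Cells with ≥ 10 % cover in 2001 are classified: **deforested** (≥ 2 %-pt
   loss), **non-deforested** (< 0.5 %-pt loss; the control pool), or buffer.
3. **Attribution (moving-window counterfactual matching).** For each
   deforested pixel, the mean ΔT of all non-deforested pixels within a
   0.25° circle (0.50° fallback) and within ±50 m elevation is subtracted
   from the pixel's own ΔT:

   ΔT_defor = ΔT_pixel − mean(ΔT_controls)

   This removes the shared background (global and regional climate change).
   The result is normalized per percentage point of loss, smoothed over a
   0.10° rolling circle (using only pixels with ≥ 5 %-pt loss, one-pass
   z > 3 outlier screen, regional-mean fallback), and multiplied back by
   each pixel's loss.
4. **Exposure and mortality.** People on deforested pixels with ΔT_defor > 0
   are "exposed". With a country/continent heat vulnerability index HVI
   (%-points of excess mortality per °C) and the annual non-accidental
   mortality rate, per pixel *i*:

       nonacc_mort_i = pop_i × rate / 100000
       f_i           = (HVI / 100) × ΔT_defor_i        (0 if ΔT_defor ≤ 0)
       CF_mort_i     = nonacc_mort_i / (1 + f_i)
       heat_mort_i   = nonacc_mort_i − CF_mort_i       = nonacc_mort_i × f_i/(1+f_i)

   The 95% CI of the mortality rate propagates linearly to low/high bounds.
5. **Reporting.** Area- and population-weighted warming, exposure counts
   above +1/+2/+3 °C, attributable deaths and rates per 100,000 are pooled
   by admin unit, region, and overall.

Because the real inputs (MODIS LST, Hansen forest change, LandScan
population, GBD mortality) are multi-terabyte downloads, the package ships
a seeded synthetic-landscape generator that emulates their statistical
structure — clustered loss, smooth background trend, warming proportional
to loss, heteroscedastic noise, clustered population, per-admin rates with
CIs — with exact ground truth, so every stage is testable offline.

## Worked example

```r
library(deforheat)

world  <- generate_world(world_params(seed = 42))  # 300 x 300 cells, ~20 s
result <- run_pipeline(world)                      # full chain, ~9 s
print(result)
format_region_report(result$report)
```

```
<pipeline_result> 1097 treated pixels (0.00% unmatched), report rows: 4
  scope pop_forest_loss pop_exposed        deaths rate_per_100k
1     1         9.3e+05     9.3e+05 170 (150-190)            18
2     2        4.91e+04    4.91e+04    20 (20-20)            44
3     3        9.16e+04    9.16e+04    30 (30-30)            33
4   all        1.07e+06    1.07e+06 220 (200-250)            21
  share_total_heat share_nonacc areawgt_dt_defor popwgt_dt_defor
1            84.7%        2.68%             1.09            1.20
2            87.0%        5.47%             1.09            1.13
3            83.5%        4.76%             1.06            1.05
4            84.7%        3.01%             1.08            1.19
```

Reading the pooled row: about 1.07 million synthetic people live on pixels
that lost ≥ 2 %-pt of forest; all of them sit on pixels with positive
attributed warming (the generated warming coefficient is positive and noise
is moderate); the area-weighted attributed warming is 1.08 °C; the central
estimate is 220 attributable deaths per year (95% CI 200–250, from the
mortality-rate CIs), i.e. 21 per 100,000 — 84.7% of the total heat-related
mortality on those pixels, the rest being background climate trend. Deaths
are rounded to the nearest ten and rates to whole numbers only at
presentation.

Ground-truth recovery on the same world:

```r
recovery_metrics(world, result$attribution, result$exposure$all)
#   bias_dt_defor rmse_dt_defor n_compared rel_err_exposed_pop
#          ~0.01          ~0.1       1097                   0
```

## Command line

```sh
inst/exec/deforheat synth --seed 42 --out world/    # write a synthetic world
inst/exec/deforheat run   --seed 42 --out run/      # run the full pipeline
```

`--config` accepts a `key = value` file (see `?read_pipeline_config`) with
every threshold of the analysis, including the sensitivity switches
(loss threshold 1 vs 2 %-pt, gain threshold 20 vs 50 %-pt, alternative year
windows, LST-to-air-temperature slope, literal-percent mortality variant).
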