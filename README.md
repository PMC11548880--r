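# foxtrot

Movement-ecology tools for birds whose migration alternates **quick**
directed legs with **slow, continuous drift** across the over-wintering
range — "foxtrot migration". The motivating system is an Arctic-breeding
raptor (the Rough-legged buzzard, *Buteo lagopus*) that flies ~1500 km
from the tundra to the mid-latitudes each fall, then keeps moving
~1000 km south-west ahead of the advancing snowline and back north-east
before spring, so that its winter range shifts geographically all
season. The package is for movement ecologists who want to estimate
this phase structure from GPS tracking tables and quantify the dynamic
winter footprint against environmental counterfactuals.

## What it computes

Given mean daily positions on a consecutive day-of-year axis (days
after 31 December continue 366, 367, ...), each bird-season is
segmented by an iterative piecewise-regression breakpoint search: for
each of the four migration dates, every integer day *b* in a calendar
search window is scored by the residual standard error of two
independent OLS lines of latitude on day (before/from *b*),

    RSE(b) = sqrt((RSS_left + RSS_right) / (n - 4)),

the minimising day wins (ties to the earliest), and a nested F test
against the single-line model validates the break. The mid-winter turn
is the day of lowest daily latitude. From the five dates the package
derives per-phase distance (great-circle, start to end), duration,
speed and initial bearing; population summaries with circular direction
statistics; monthly 95% minimum convex polygons (retain the ceil(0.95 n)
positions nearest the centroid, convex hull in the lon/lat plane) of
the pooled wintering population; mean fractional snow cover inside each
footprint; counterfactual exposure series (stay where fall migration
ended vs fly directly to the far south-west); and a regression of
month-to-month range displacement on snow cover. A seeded synthetic
generator (tracks + snow rasters + land cover) reproduces the study
conditions so everything is testable offline.

## Worked example

```r
library(foxtrot)

cfg    <- sim_config(n_birds = 10, seed = 7)   # published study parameters
tracks <- simulate_tracks(cfg)                 # hour-stamped position records
daily  <- preprocess_tracks(tracks)            # dedupe, daily means, DOY axis
fit    <- fit_foxtrot(daily)                   # breakpoint search per bird
summary(fit)
```

```
Foxtrot migration fit: 10 bird-season(s), 0 excluded

     boundary mean_doy sd_doy  n mean_lat sd_lat mean_lon sd_lon
   fall_start    269.9   4.33 10    68.24   1.10    56.78   6.27
     fall_end    287.1   3.21 10    52.53   3.38    48.66   5.93
  winter_turn    379.0  33.06 10    49.62   3.56    39.23   7.58
 spring_start    485.5   4.30 10    56.36   3.41    63.81  16.72
   spring_end    503.1   4.09 10    71.92   2.87    69.90  17.02

Piecewise vs simple model: 100% of per-date comparisons with p < 0.001
```

Fall migration starts around day 270 (late September) at the Arctic
colonies and ends around day 287 at ~52.5°N; the slow drift bottoms out
near day 379 (mid-January here) and spring migration runs from late
April (485) to mid-May (503). Every per-bird piecewise fit beat the
single-line model at p < 0.001.

```r
summarize_phases(phase_metrics(fit))
```

```
Phase metrics across 10 birds (mean +- sd):

  Qf    1801 +- 429 km   17.2 +-  3.9 d  104.6 +- 6.8 km/d  dir 198.1 deg
  S1     741 +- 271 km   91.9 +- 34.9 d    8.1 +- 0.6 km/d  dir 244.5 deg
  S2    1763 +- 578 km  106.5 +- 35.1 d   16.6 +- 0.8 km/d  dir  53.9 deg
  Qs    1754 +- 231 km   17.6 +-  2.5 d   99.9 +- 3.2 km/d  dir   6.8 deg

Pooled one-part phases:
  quick   1778 +- 292 km   17.4 +-  2.7 d  102.3 +- 3.2 km/d
  slow    1252 +- 158 km   99.2 +-  2.7 d   12.3 +- 0.5 km/d

Quick is 526 +- 375 km longer and 82 +- 4 days shorter than slow
```

The quick phases run at ~100 km/day heading SSW (198°) in fall and N
(7°) in spring; the slow phases drift at 8–17 km/day WSW (245°) then
ENE (54°) — the foxtrot signature of fast and slow steps in different
directions.

```r
snow <- simulate_snow(cfg)
round(scenario_series(daily, snow), 1)
```

```
  month realized stay_north direct_southwest
1    10      6.4       26.5              2.2
2    11     10.5       71.4             34.7
3    12     41.2       84.7             57.2
4     1     67.7       91.3             70.8
5     2     78.2       93.1             74.8
6     3     78.9       88.6             65.1
7     4     67.7       69.5             32.0
```

Had the birds stayed where fall migration ended (`stay_north`), they
would have sat in 91–93% snow cover in mid-winter instead of the ~78%
they actually experienced; the drift keeps them near the snowline
without paying the full cost of wintering in the far south-west.

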