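---
title: "Methods: segmenting foxtrot migration and quantifying the dynamic winter range"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting foxtrot migration and quantifying the dynamic winter range}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The movement pattern and the model

Some Arctic-breeding raptors do not sit still on their "wintering
grounds". After a quick fall migration of roughly 1500 km from the
tundra to the mid-latitudes, they keep drifting south-west ahead of the
advancing snowline for months, turn around in mid-winter, and drift
north-east again before a quick spring migration home — quick and slow
steps alternating like a foxtrot. The slow drift makes the
over-wintering range *dynamic*: a single mid-winter survey sees only the
south-western corner of a footprint that moves all season.

`foxtrot` estimates this annual phase structure from GPS tracking data
and quantifies its environmental context. The season model has five
boundary days per bird on a *consecutive* day-of-year axis (days after
31 December continue 366, 367, ...):

* `fall_start`, `fall_end` — the quick fall migration (Qf);
* `winter_turn` — the day of lowest mean daily latitude, splitting the
  slow phase into a south-westward part (S1) and a north-eastward part
  (S2);
* `spring_start`, `spring_end` — the quick spring migration (Qs).

### Breakpoint estimation

Each of the four migration dates is estimated separately per
bird-season by a piecewise-regression breakpoint search. For a candidate
break day $b$ inside that date's search window, two independent OLS
lines of latitude on day are fitted to the days before and from $b$
(four parameters, a discontinuity is allowed), and the residual standard
error $\sqrt{(RSS_L + RSS_R)/(n-4)}$ is evaluated on an integer-day
grid; the feasible candidate with the smallest RSE wins, ties going to
the earliest day (numerically, a candidate must improve the incumbent by
more than $10^{-9}$). A nested F test against the single-line model on
the same data slice records whether the break is supported
($F = \frac{(RSS_0-RSS_1)/2}{RSS_1/(n-4)}$).

The default search windows are 5 Sep–5 Oct and 5 Oct–5 Nov for the fall
dates and 10 Apr–10 May and 10 May–10 Jun for the spring dates. The
data slice fitted for each date extends `fit_margin` (default 30) days
beyond its window *only on the side away from the adjacent migration
date*, i.e. it is clipped at the shared window edge (5 Oct, 10 May).
This is deliberate: a symmetric slice for the fall-start date would
reach past most birds' fall *end*, so the two-segment model would face
three slopes and place the break with a multi-day bias (up to nine days
in simulation). With the directional slice each fitted slice contains a
single slope change and noiseless recovery is exact up to the one-day
ambiguity of the knot itself (the boundary day lies on both segments,
so breaks at the knot and one day later fit equally well).

The winter turn is the argmin of daily latitude between the estimated
fall end and spring start (ties to the earliest day). No regression is
involved, so its precision is set by the latitude noise against the
very shallow slope of the slow phase: with the default simulation
conditions (8 km/day drift at bearing 251°, i.e. ≈0.02° latitude/day,
against 0.3° daily position noise) the estimate scatters with a median
error of ≈3–5 days and a ninetieth percentile near two weeks. That is a
property of the method on such data, not of the implementation, and the
published between-bird spread of this date (±40 days) dwarfs it.

### Phase metrics

For each phase, distance is the great-circle distance between the mean
daily positions on the phase's two boundary days (spherical haversine,
Earth radius 6378.137 km), duration the day difference, speed their
ratio (so speed × duration = distance holds exactly), and direction the
initial great-circle bearing from start to end. Directions are
summarised with circular statistics (vector mean; circular sd
$\sqrt{-2\ln \bar R}$), with arithmetic mean ± sd also reported for
comparability with published tables. Quick (Qf, Qs) and slow (S1, S2)
phases are pooled per bird ("one part" = the mean of the bird's two
parts) before across-bird summaries and contrasts.

### Range dynamics and snow counterfactuals

The monthly population footprint is a 95% minimum convex polygon: all
birds' daily positions in a calendar month are pooled, ranked by
great-circle distance to their arithmetic-mean centroid, the nearest
⌈0.95 n⌉ retained (ties keep the earlier record), and the convex hull
taken in the lon/lat plane. Mean fractional snow cover inside a
footprint is the unweighted mean of raster cells whose centres fall
inside or on the hull (cell-centre-in-polygon, boundary inclusive).

Three exposure series are compared from October to April: *realized*
(each month's raster inside that month's MCP), *stay-north* (each
month's raster inside the fixed MCP of pooled October + April
positions — where the birds arrive and depart), and *direct-southwest*
(the fixed MCP of pooled January + February positions — the
south-western extreme). The two anchor-month pools follow the study
design this package reimplements; with the wording ambiguous between
one pooled MCP and two averaged ones, one pooled MCP per counterfactual
was chosen for a single fixed footprint. Month-to-month displacement is
the great-circle distance between consecutive monthly centroids, and is
regressed (OLS) on the snow cover at the first footprint and the
snow-cover difference.

Where the original analysis used binomial mixed models over snow
presence/absence and `lmer`/`emmeans` machinery for phase contrasts,
this package deliberately uses per-bird estimates with paired and Welch
t procedures, a seeded pixel bootstrap for footprint means, and nested
F / likelihood-ratio tests for model comparison: the estimands (mean
phase contrasts, exposure differences) are the same, the per-bird route
is transparent and dependency-free, and the model-comparison contract
(piecewise beats a single line at p < 0.001) is preserved per fit.

## The synthetic study system

The generator exists so the whole pipeline is testable without any
downloads; its defaults *are* the published study conditions wherever
those are stated.

* 43 birds (35 females, 8 males), breeding origins near 68.5°N 58°E
  (sd 0.7° / 6° — the spread of the four Arctic study colonies).
* Phase speeds 107, 8, 17, 100 km/day and bearings 198°, 251°, 57°, 7°
  for Qf, S1, S2, Qs.
* Boundary days centred on 271, 285, 401, 482, 500 (consecutive DOY)
  with between-bird sds 11, 11, 40, 7, 8 days. Because the published
  duration spreads (14 ± 4 days fall, 18 ± 4 spring) are much tighter
  than the boundary-day spreads, each quick phase's end day is drawn as
  start + duration; draws are rejected until every migration date lies
  at least two days inside its search window (a break on the outermost
  window days leaves fewer than two observations on one side of the
  fitted slice and is unrecoverable even without noise) and the turn
  lies inside the winter.
* Within a phase the bird travels along a *single great-circle arc*
  whose initial bearing at the phase start is the configured direction.
  Daily steps at a constant compass bearing were considered and
  rejected: they trace a rhumb-like path whose start-to-end great-circle
  bearing differs from the configured one by meridian convergence
  (≈11° on the S2 leg), which would make the configured directions
  unrecoverable by the package's own metric definition.
* Observed positions add independent Gaussian noise (default 0.3°) to
  each day's true latitude and longitude — a simple stand-in for
  within-day movement scatter, adequate at mid-latitudes and applied in
  degrees rather than metres for transparency. 1% of rows are
  duplicated verbatim to exercise timestamp de-duplication.
* Monthly snow is `100·plogis((lat + 0.25·(lon − 49) − s_m)/1)` percent
  plus clipped N(0, 3) cell noise on a 0.5° grid: a snowline tilted in
  the lat/lon plane so it advances towards the *south-west* from
  October (s = 68.5 at 49°E) to February (46) and retreats north-east
  to April (55). The tilt matters: with a purely latitudinal snowline
  the south-western counterfactual footprint would not be milder than
  the realized range, contrary to the system being emulated. The path
  was calibrated once against the published exposure anchors (realized
  October ≈ 5%, February as high as the footprint geometry allows; see
  limitations).
* Land cover is zonal with i.i.d. within-band cell draws: wooded-fields
  mosaic below 57°N (63% grassland, 28% cropland, 5% forest), ≥90%
  forest taiga between 57 and 66°N, and shrub/grass tundra above.

Season years run 1 July–30 June (all phases fall strictly inside one
season, far from any migration window), dated in 2021/22 — a non-leap
pair, matching the package's fixed 365-day DOY convention under which
the published date↔DOY anchors (28 Sep = 271, 12 Oct = 285, 27 Apr =
117, 15 May = 135) reproduce exactly; 29 February, when it occurs in
real data, is folded onto day 60 and documented as sharing 1 March's
index. Daily positions are binned by UTC calendar day, duplicates keep
the first record in file order, and daily longitudes are arithmetic
means (fixes within a day span ≪ 1°; the antimeridian is not handled).

### What the generator does and does not emulate

It reproduces the four-phase kinematics, between-bird phenological
variation, the advancing/retreating snowline, and the vegetation
zonation — enough for the estimators' recovery properties to be
meaningful. It does not attempt wind, stopovers, foraging excursions,
mortality, tag failure, hourly fixes, or any behavioural response of
birds to the simulated snow (movement and snow are independent given
the calendar, so the displacement-vs-snow regression on synthetic data
estimates a month-confounded association, not a causal response).
Passing recovery tests on this generator therefore shows the estimators
are correct and well-calibrated under the stated structure, not that
real tracking data meet that structure.

## Numerical and design choices

* Integer-day candidate grid (daily positions make finer resolution
  meaningless); a candidate needs ≥2 points strictly on each side and
  n > 4 overall, otherwise it is infeasible.
* Spherical geometry throughout, radius 6378.137 km, delegated to
  `geosphere` with `f = 0` where the function is ellipsoidal by
  default; ellipsoidal geodesics differ by <0.5% at these scales.
* MCP retention exactly ⌈level·n⌉; hull vertices are retained points;
  degenerate (collinear) hulls are flagged.
* Rasters are plain in-memory matrices with cell-centre registration
  and ESRI ASCII grid text serialisation; categorical lookup is
  containing-cell with edge ties to the smaller row (southern), then
  column (western) index.
* The MODIS-style LAI legend is merged to five classes: four forest
  types + savanna → forest; water, non-vegetated and unclassified are
  excluded from composition denominators (non-vegetated is not among
  the five published classes; excluding it is this package's reading).
* Tests and the acceptance script run the full pipeline at the study's
  own size — 43 birds × 365 days and 0.5° rasters — which completes in
  seconds; the statistical calibration suite uses 1000 null replicates.

## Known limitations

* **Winter-turn precision.** See above; per-bird S1/S2 metrics inherit
  some of this scatter, and the latitude-argmin selection biases the
  turn-day position slightly southward (the selected day tends to carry
  a negative noise excursion).
* **Mid-winter counterfactual near-coincidence.** In January–February
  the realized footprint and the direct-southwest counterfactual are
  the same region by construction (the counterfactual is *defined* by
  the January + February range), so their exposure difference there is
  a knife-edge quantity of a few percentage points either way. For any
  snow field that increases along a single NE–SW coordinate, requiring
  realized > direct-southwest in *both* months is impossible: both
  contrasts compare the same two footprints with opposite signs
  required. The robust, reproducible orderings are stay-north ≫
  realized in mid-winter and realized > direct-southwest over the
  season as a whole, and those are what the package's property tests
  assert; the acceptance suite additionally records the strict
  month-wise reading, which fails for January, as an honest negative.
* **Snow saturation shortfall.** The synthetic February exposures
  (≈76% realized / ≈93% stay-north) fall short of the published 85.2% /
  99.5% because the synthetic monthly hulls span a wider range of the
  snow coordinate than the real ones (the ±40-day turn spread sends
  some birds far north-east by February); narrowing the snowline width
  further does not close the gap.
* **Slow-phase forest share.** The generator's S2 leg, run at the
  published speed and bearing between the published boundary days,
  re-enters the taiga before spring, so the synthetic slow-phase forest
  share (≈20%) exceeds the published 4.9%; the published phase table is
  not closable as a constant-velocity trajectory (its own boundary
  days imply an 81-day S2 where 66 ± 6 is printed), and the boundary
  days were taken as primary.
* Longitude averaging and the MCP plane treat longitude as Euclidean;
  ranges spanning the antimeridian are out of scope.
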