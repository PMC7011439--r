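---
title: "Methods: fine-scale movement and activity analysis for tracked demersal sharks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale movement and activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

trackpatch analyses paired data from continuous active acoustic tracking
(a vessel following a tagged shark, logging its own geo-position on every
transmitter detection) and an animal-borne accelerometer sampling three
axes at 25 Hz together with depth and temperature. The scientific target
is the nocturnal movement strategy of a demersal, non-obligate ram
ventilating shark: where it rests by day, when it departs after sunset,
where it concentrates search effort at night (area-restricted search,
ARS), how active it is within those patches, and how activity relates to
time of night, temperature and depth. This vignette documents the models,
the tunable parameters, and the design decisions taken where the
methodology leaves genuine freedom.

## Telemetry handling

Detections carry the receiver's gain and signal strength. Only
detections at gain 0 dB with signal strength in the closed interval
[80, 105] dB are retained (`filter_detections()`); in range tests this
combination corresponds to a positional accuracy of about 5-10 m. The
interval is treated as closed on both ends — the inclusive reading of
"between" retains boundary detections. The vessel position is taken as
the shark's position; no state-space smoothing is applied.

Timestamps are stored in UTC throughout and rendered to local clock time
only through an explicit UTC offset (tests use -7 h, local daylight
time, which is the only offset consistent with the sunrise range
05:42-07:07 over a June-October season at a southern-California site).
Sunrise and sunset come from NOAA solar geometry at zenith 90.833
degrees (`solar_times()`), accurate to well under a minute; a diel split
(`split_diel()`) alternates day (sunrise to sunset) and night periods.
Partial tagging/recovery day periods count as day periods, but only
complete nights are counted — with that rule a 24 h or 38 h track
contributes 2 day + 1 night and a 48 h track 3 day + 2 nights, which is
the only reading that reproduces the 49 day / 30 night period counts of
a 19-shark spatial analysis set alongside one 38 h track.

Cohort inclusion (`cohort_filter()`) is driven by removal-note codes:
tag loss removes a shark from everything, track loss from spatial
analyses, logger malfunction from accelerometer analyses; the paired set
is the intersection.

## Space use: Brownian bridge kernel utilization distributions

Between consecutive detections the animal is modelled as a Brownian
bridge: at fractional time $\alpha$ of a pair spanning $T$ seconds the
position is Normal around the linear interpolation with variance

$$\sigma^2(\alpha) = T\,\alpha(1-\alpha)\,\sigma_1^2 +
\left[(1-\alpha)^2 + \alpha^2\right]\sigma_2^2,$$

where $\sigma_1$ (m s^-1/2^) captures mobility and $\sigma_2$ is the
positional error SD (default 7.5 m, the midpoint of the 5-10 m
accuracy envelope; configurable). $\sigma_1$ is estimated by maximising
the leave-one-out likelihood of the odd-indexed detections given their
neighbours (`estimate_sig1()`, Brent search on [1e-4, 10], tolerance
1e-6). Note this likelihood deliberately omits the observed point's own
error term — the standard construction — so on data where $\sigma_2$
rivals inter-fix displacement the estimate absorbs part of the noise;
parameter-recovery tests therefore run at small $\sigma_2$.

The UD (`bbkud()`) is the time-weighted average of the bridge densities,
integrated over $\alpha$ with a 10-step midpoint rule per pair, on a
metric grid (default 5 m cells, chosen to resolve core areas down to
~5e-5 km^2^; the grid is padded by 3 bridge SDs). Isopleths
(`ud_contour()`) take the smallest set of cells reaching the target mass,
with density ties broken in row-major order so results are reproducible;
95% estimates daily activity space and 50% the core. Region overlap
(`overlap_area()`, `core_overlap()`) is computed by rasterizing both
regions on a shared fine grid (default 1024 cells across the joint
bounding box) — contour regions are natively cell sets and patch/contour
unions are non-convex, so a raster intersection is both simpler and
adequate: its error is about half a cell along the perimeter, well under
1% at the default resolution.

## ARS detection: first passage time and Lavielle segmentation

First passage time (`fpt()`) at radius $r$ around a track point is the
time between the first backward and first forward crossings of the
circle, with crossings located by linear interpolation along segments;
values at the path ends where no crossing exists are undefined and are
excluded (never imputed). The ARS scale (`ars_scale()`) is the radius
maximising the variance of log FPT over a 5-100 m sweep, capped by the
equivalent-circle radius of the nighttime core area,
$\sqrt{A_{50}/\pi}$; a flat variance profile (max/min < 1.2) sets a
low-signal flag and no patches are reported.

The FPT series at the chosen scale is segmented by the Lavielle
penalized-contrast method (`lavielle_segment()`): an exact dynamic
program minimises the within-segment sum of squares about segment means
for each $K \le K_{max} = 20$ with at least `Lmin = 10` relocations per
segment (the minimum-length control is interpreted in relocations, not
metres, because the segmentation operates on an indexed series; both
readings are close at ~30 s relocation spacing). The contrast is
standardized to $[0,1]$, and $K_{opt}$ is the last $K$ whose scaled
second difference $D(K) = (\tilde J(K-1) - 2\tilde J(K) + \tilde
J(K+1))(K_{max}-1)$ exceeds $S = 0.75$; a series with no contrast yields
$K_{opt} = 1$.

Turning segments into patches (`extract_patches()`) requires a
deterministic stand-in for what is, in field practice, a visual GIS
assessment. Design choices here, each measured against simulation ground
truth:

* **Movement path, not night window.** Patch detection runs on the
  nighttime movement path: `trim_shelter()` removes the leading and
  trailing spans within 50 m of the first/last anchor positions.
  Shelter occupancy inside the night window otherwise registers as an
  enormous FPT plateau (a false "patch" at the daytime shelter) and
  shrinks the core-area radius cap toward the noise scale.
* **ARS rule.** The default separates segment means into a low (transit)
  and high (ARS) group by a two-group split of log segment means,
  requiring at least two-fold contrast. A plain above-median rule is
  available (`rule = "median"`) but splits any patch that occupies more
  than half the series — the median then falls inside the patch plateau
  — which halves measured residence; the grouped split recovers planted
  patch counts in 95% of simulated nights versus ~65% for the median
  rule. A fraction-of-maximum rule is also provided.
* **Merging and floors.** Adjacent ARS segments merge; ARS runs whose
  centroids fall within min(3 scale radii, 100 m) are one revisited
  patch and merge too; runs shorter than 10 min are dropped (observed
  residences start around 0.2 h — a shorter high-FPT blip is a pause,
  not patch use); span boundaries are trimmed to 2.5 scale radii around
  the FPT-weighted centroid, because segmentation granularity otherwise
  lets the approach transit bleed into the patch and drag its centroid.
* Patch geometry: minimum convex polygon (convex hull; shoelace area),
  centroid as the mean of member coordinates, residence from first/last
  member timestamps. Degenerate (<3 distinct points) patches get area 0
  and a flag.

Straight-line distances between the daytime shelter centroid, patch
centroids and the next morning's shelter (`patch_distances()`) use the
local planar projection; at site scale (<5 km) planar and great-circle
distances agree within 0.1%.

## Activity: ODBA, wavelet ethogram, binary classification

Static acceleration is a centred 2 s box smoother per axis (49 samples
at 25 Hz; the window shrinks symmetrically at the edges, which affects
only the first and last second), and dynamic acceleration is the
residual, so the decomposition is exactly additive
(`separate_acceleration()`). ODBA is the sum of absolute dynamic axes,
averaged per second (`odba()`); a sway-only sinusoid of amplitude $A$
yields mean ODBA $2A/\pi$, which anchors the generator's amplitude
calibration and the analytic tests.

The per-second ethogram uses a Morlet continuous wavelet transform
(centre frequency 6) of the sway axis at 16 log-spaced periods within
the 0.5-2 s tailbeat band (`wavelet_spectrum()`). Moduli are normalised
so a unit-amplitude in-band sinusoid reads 1 g (the response of the
analytic Morlet at the matching scale is inverted per scale), which
makes the resting-cluster threshold meaningful in g. Per-second frames
are clustered by k-means with k = 10 and 25 restarts under a fixed seed
(`cluster_ethogram()`), per individual — spectra are not comparable
across animals. On streams beyond 10,000 s the centres are fitted on a
10,000-frame subsample and all seconds assigned to the nearest centre.
Clusters whose centre peak amplitude is below 0.1 g are resting
clusters (the field procedure labels them by eye; the threshold is
configurable), and every second gets a binary resting/active state
(`classify_activity()`). On well-separated two-state streams the binary
accuracy exceeds 99%; boundary seconds between states are where the
residual errors live, because the wavelet envelope smears a second or
two across transitions.

## Patch activity typing

`join_patch_activity()` aggregates the per-second states, ODBA, depth
and temperature over each patch's [entry, exit]; patches with more than
5% of seconds missing are excluded, not imputed. `classify_patch()`
then applies, in order: **resting** — at least 95% of seconds
motionless, at least 95% of seconds under 0.2 g, and within-patch depth
range under 1.0 m (the operational form of "no discernible depth
change"); otherwise **episodic burst** if at least one burst run
(per-second ODBA >= 2 g sustained 1-5 s) occurs alongside at least 30%
resting time; otherwise **moderate consistent activity**. Resting
patches are flagged out of downstream patch statistics — a shark
motionless for 95% of the time may simply be sheltering. The burst
definition is a documented proxy for what was originally a visual call;
every threshold is an argument. Planted-class recovery on simulated
patches is 93%; the residual confusions are large resting patches whose
entry interval includes the swim to the resting spot (the depth-range
criterion then fails even though the shark rested throughout).

## Statistics

`fit_lme()` fits random-intercept linear mixed models by REML for
estimates and refits by ML for AIC and total deviance (-2 maximised
log-likelihood), with Type II Wald chi-squared tests per fixed term.
Deviance explained is $100(\mathrm{dev}_0 - \mathrm{dev}_m)/\mathrm{dev}_0$
against the intercept-plus-random-effect null, reported to 2 decimals
(`deviance_explained()`).

`fit_activity_smooth()` models 5-min-mean activity series with a
penalized regression spline (cyclic over 24 h for time of day;
`hours_after_sunset` is the recommended axis for nighttime-only series,
where a cyclic day-scale basis wastes resolution on unobserved hours),
a per-individual random intercept, and an AR1 working correlation whose
coefficient is the pooled within-individual lag-1 autocorrelation of
first-pass residuals (`acf_lag1()`: mean-centred, denominator n).
Smoothing is chosen by GCV. The default basis dimension k = 8 resolves
features wider than about a sixth of the predictor range; recovering
~45-min transit peaks in a 10 h night needs k = 14, which the examples
use. Peak locations are read off the fitted curve with a topographic
prominence filter (`smooth_peaks()`).

## The synthetic-data generator

`simulate_night_track()` produces a state-switching correlated random
walk on a local tangent plane (equirectangular; exact enough below 5 km
extents): daytime shelter rest; departure drawn 3.4 +/- 2.2 h after
sunset; directed transit at 0.35 m/s with small heading noise toward
1-3 patch centres 150-1200 m apart (1 patch on 79% of nights, 2 on
14%, 3 on 7%); within-patch movement by regime; return to a new shelter
3.5 h (SD 2.6 h) before sunrise. Patch radii are log-normal with mean
~31 m clamped to [8, 112] m; residences are log-normal around 2.3 h
clamped to [0.3, 5] h; infeasible schedules shrink residences, then
distances. Regimes follow the observed patch-class mix (54% moderate,
33% episodic burst, 13% resting): moderate patches are a confined
tortuous walk at 0.25 m/s inside 0.85 of the patch radius; burst
patches alternate ~4 min anchored rests with repositioning swims between
anchors, with 1-5 s burst runs embedded at 0.03 s^-1^; resting patches
hold one anchor near the centre (so their depth stays flat). Detections
are emitted every 2 s with isotropic N(0, 7.5 m) noise per coordinate
plus ~8% deliberately low-quality rows for the filter to remove.

`simulate_biologger()` renders the per-second behavioural schedule at
25 Hz: gravity projected through a smoothed pitch posture, a sway
sinusoid at the tailbeat period (default 1 s) whose amplitude is set so
realised mean ODBA hits the per-state targets (rest 0.03 g, transit
1.0 g, in-patch moderate 0.8 g, burst 2.5 g; mean |A sin| = 2A/pi),
and 0.01 g sensor noise per axis. Depth follows a smoothstep bathymetry
(6 m on reefs to 35 m in channels over 300 m) along the true path,
and temperature a logistic thermocline (21 to 12 degrees C, midpoint
25 m, width 8 m), so temperature never increases with depth and
transits cross deeper, colder water — the structure the smooth models
are asked to recover.

What the generator does **not** emulate: tides and internal waves,
receiver drop-out structure (gaps are i.i.d., not sea-state driven),
prey fields, individual personality beyond the drawn schedule
parameters, tag-effect behaviour on the tagging day, and any coupling
between temperature and behaviour. Passing recovery tests therefore
shows the estimators are correct under the stated statistical structure
— not that real data meet that structure.

## Problem sizes and numerical choices

Validation experiments use: 20 simulated nights for spatial recovery
(patch count, centroid, residence, false positives), 30 planted patches
for class recovery, 6 individuals for the bimodal activity fit, n = 1e4
for AR1 recovery, and a 15-shark synthetic cohort for the day/night
activity-space contrast. Detection streams are thinned to 30 s
relocations for FPT/segmentation and 60-120 s for bridge UDs; UD cells
are 5 m by default and 10 m in the cohort-scale experiments. Ties in
isopleth ranking are row-major; k-means uses MacQueen updates with 25
restarts under a fixed seed; the Lavielle DP is exact, not heuristic.
Degenerate inputs (constant series, coincident points, all-rest
streams, single-shark cohorts) return defined results or named errors,
exercised in the test suite.
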