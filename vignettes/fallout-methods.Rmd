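---
title: "Methods: flight metrics, light exposure and grounding-rate inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flight metrics, light exposure and grounding-rate inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallout)
```

This vignette is the package's own account of the models and procedures it
implements, the assumptions they rest on, and the design choices made where
the underlying field methodology leaves the design open.

## 1. The scientific setting

Petrel fledglings fly from their natal burrow to the sea once, at night.
Artificial lights can attract and disorient them, grounding them inland
("fallout"). The analytical questions are: how do maiden flights look
(timing, length, straightness, speed); how much light pollution do birds and
colonies experience; which colony-level covariates (elevation, distance to
sea, light metrics) explain per-colony grounding rates; and what breeding
population do rescue totals imply.

Three data streams feed these questions: GPS tracks at 10–30 s fix
intervals, a nocturnal radiance raster (nW sr⁻¹ cm⁻², VIIRS-like), and
banding/recovery tables per colony. No public deposit of such raw data
exists, so the package carries a synthetic nightscape generator
(section 4) that reproduces the *statistical structure* of the system and
makes the pipeline testable end to end.

## 2. Flight metrics

For a track of fixes \(p_1,\dots,p_n\) (WGS84 lon/lat, UTC times):

* cumulative length \(L=\sum_i d(p_i,p_{i+1})\) and straight length
  \(S=d(p_1,p_n)\), with \(d\) the geodesic on the WGS84 ellipsoid
  (`geosphere::distGeo`);
* tortuosity \(T = 1 - S/L \in [0,1]\): 0 is a straight flight, 1 a closed
  loop. \(S \le L\) holds by the metric triangle inequality and is asserted
  on every simulated track in the test suite;
* timing: minutes from apparent sunset to the first fix. Sunset is computed
  with the NOAA solar-position equations at zenith 90.833° (refraction plus
  solar radius), iterated so the ephemeris is evaluated at the sunset
  estimate itself. The test suite checks it against an independent
  low-precision ephemeris (Spencer Fourier series) to within 2 minutes.
  Negative timings (pre-sunset departures) are kept and reported, not
  clamped — the generator can produce them even though observed minima were
  positive;
* speed: mean ground speed over the segment ending at the first *on-water
  rest*, defined as the first fix over sea whose incoming segment speed
  falls below 5 km/h (configurable). Birds that land on the water stop
  moving at flight speed, and including drift would bias speed downward.
  The field methodology does not define rest detection; this rule is ours.

Internally all metric arithmetic on rasters uses a local equirectangular
projection with WGS84 meridional/prime-vertical scales at the reference
latitude; the tests verify it agrees with full geodesics within 0.1 % at
study scale (≤ ~50 km), while reported distances always use the geodesic.

## 3. Exposure extraction

* **Point exposure** is the value of the raster cell containing the point —
  no interpolation, matching the "pixel value intersected with the colony
  centre" convention. Cells are half-open
  (\([x, x+s) \times (y-s, y]\)), so a point on a shared edge belongs to
  exactly one cell; the choice is arbitrary but deterministic.
* **Track exposure** collects the set of distinct cells crossed by the
  polyline via an exact grid traversal (Amanatides–Woo stepping) and takes
  the unweighted mean and max: each traversed cell counts once regardless of
  dwell length. A length-weighted mean is available
  (`sample_track(..., weighted = TRUE)`) but the unweighted version is
  canonical, since "intersecting the track with the image" describes a cell
  set, not a time integral.
* **Buffer statistics** (default 3 km) include every cell whose *centre*
  lies within the geodesic radius — no partial-area weighting, the simplest
  defensible reading. The containing cell is always included, so a radius
  smaller than half a cell degenerates to the single pixel.
* **Distance to sea** is the minimum geodesic distance to the centre of any
  sea cell, where sea = nodata or elevation ≤ 0 (a single-raster world
  definition). Only coastline sea cells (those touching land) need be
  scanned.
* **Colony delimitation** uses single-linkage clustering with a 1-km
  threshold: burrows share a colony iff a chain of ≤ 1 km links connects
  them. Chaining is a deliberate, documented property: burrows 1.8 km apart
  may share a colony through an intermediate. Colonies are relabelled
  south-to-north so the partition is invariant to input order.

## 4. The synthetic nightscape

What it emulates — and why those defaults:

| Parameter | Default | Rationale |
|---|---|---|
| peak elevation | 3,718 m | a large, steep volcanic island |
| DEM cell | 25 m | the resolution of the island DEM used in this field |
| island radius | 12 km | keeps the below-1,000 m nesting band several km wide |
| elevation profile | \((1-d/R)^{1.8}\) | convex shield-volcano profile; a linear cone pins all low-elevation land to a thin coastal strip |
| radiance ceiling | 103.6 nW sr⁻¹ cm⁻² | brightest urban pixel on an intensely lit island |
| light placement | ring at 0.82–0.97 R | coastal towns and resorts |
| light kernel | Gaussian, σ = 400 m | town-scale glow at 25-m cells |
| departures | zero-truncated normal, realised mean ± SD = 161.2 ± 153.8 min | the published sample statistics of burrow departure after sunset |
| cruise speed | 44.79 km/h | mean observed first-flight ground speed |
| grounding threshold | 18 nW sr⁻¹ cm⁻² | radiance level above which most groundings occurred |
| sensing radius | 16 km | maximum observed grounding distance; no perception model exists, so the observation bounds it |

The departure law deserves a note: the published 161.2 ± 153.8 are sample
statistics of the non-negative departure delays. A normal with *parent*
parameters (161.2, 153.8) truncated at zero has realised mean 183.9 and
puts only 47 % of departures within 3 h of sunset, contradicting the
observation that most birds leave in the first three hours. We therefore
solve the truncated-moment equations for the parent parameters so the
*realised* mean and SD equal the printed values; the resulting law is
strongly right-skewed with its mode at zero (66 % of departures within
3 h), matching the shape of the observed departure histogram.

Flights are a biased correlated random walk: the new heading is the
vector-sum mixture of the previous heading (weight = persistence, default
0.85), the seaward bearing — steepest DEM descent — (weight 0.6), and the
bearing to the brightest light within the sensing radius, weighted by
`light_attraction_weight ×` the bird's local radiance normalised by the
raster maximum (so birds in dark interior fly seaward, birds over lit areas
are captured). Angular noise has SD `0.4 × (1 − persistence)` rad so a
fully persistent walk is exactly straight. Per 30-s step the grounding
hazard over land is `0.15 × max(0, radiance − 18)/18`, clipped to [0, 1] —
linear in radiance excess, the simplest hazard consistent with "most
groundings above 18". A flight ends at grounding, after 1.5 km flown over
open sea (escape), on leaving the raster, or at a 10,000-step cap (logged,
counted as reaching the sea). The hazard applies only after the first step,
so a bird cannot "ground" in its own burrow.

Per-colony recoveries are binomial with
\( \mathrm{logit}(p) = \beta_0 + 0.0004\,d_{\text{sea}} + 0.0036\,e \)
(slopes in m⁻¹, the fitted estimates for the two covariates that best
explained observed grounding rates). The intercept \(\beta_0 = -5.0\) was
calibrated once so that the expected pooled recovery rate over default
colony spreads is ≈ 0.14, the published recovery rate; it was not revisited
afterwards.

One RNG substream is derived per bird from `(seed, bird index)`, so
enlarging a cohort never perturbs earlier birds; every stochastic function
takes an explicit seed and restores the caller's RNG state.

What the generator does **not** emulate: wind (a major real covariate of
fallout intensity), moonlight, multi-night behaviour after reaching the
sea, terrain shielding of light visibility, and GPS measurement error.
Passing tests therefore demonstrate that the pipeline's *estimators and
tests* behave correctly on data with the assumed structure — not that the
walk model is a faithful behavioural model of real fledglings. The
attraction mechanism in particular (continuous taxis vs threshold capture)
cannot be constrained by recovery data; the mixture walk is one admissible
choice.

## 5. Statistical machinery

* **Randomisation tests** compare group means without replacement. With
  pooled size *n* and group size *n₁*, all \(\binom{n}{n_1}\) reassignments
  are enumerated when that count is ≤ 200,000 — so an 18/13 split (8,568
  arrangements) enumerates exactly while a 32/20 split (225,792,840) is
  sampled with 9,999 iterations. Exhaustive p-values are exact rationals;
  Monte-Carlo p-values use (b+1)/(m+1), which counts the observed
  arrangement and can never be zero. Two-group comparisons default to
  two-sided (group differences are undirected); the Spearman tests are
  one-tailed, the direction being the point of the hypothesis.
* **Yates χ²** clamps the continuity correction at |O − E| so
  near-proportional tables cannot produce a negative corrected deviation.
* **Grouped-binomial GLMs** use the two-column response (recovered,
  not recovered) with logit link, fitted by IRLS (`stats::glm`,
  ε = 10⁻¹²). The test suite cross-checks the fits against a direct BFGS
  maximization of the binomial log-likelihood (agreement within 10⁻⁶) —
  two independent routes to the same MLE. Complete separation is detected
  by unbounded fitted logits (|η| > 25) and reported as an error naming the
  covariate. AICc counts k = intercept + slope (dispersion fixed at 1) and
  n = number of colonies, not birds — the standard choice for grouped
  binomial data, flagged here because the source methodology is silent.
  CIs are Wald (±1.96 SE); profile CIs can be asymmetric where Wald CIs are
  not, a known divergence we do not attempt to reconcile.
* **VIF** is 1/(1 − R²ⱼ) from OLS of each covariate on the others; on a
  radial island elevation and distance to sea are strongly collinear, which
  is exactly why only univariate candidate models are ranked.
* **Population back-calculation**: pairs = rescued / (grounding rate ×
  breeding success), floored to the nearest hundred for reporting (the
  convention that reproduces published ranges); the raw quotient is also
  returned. With rate 0.14 and success 0.75 the arithmetic is exact and
  deterministic.

## 6. Numerical and degenerate-input choices

* Tortuosity is clipped to [0, 1] against ellipsoid rounding on two-fix
  tracks; a zero-length track is an error (tortuosity undefined).
* Raster cell membership at shared edges follows the half-open convention
  (east/south cell wins); the grid walk and the point sampler share it.
* Monte-Carlo comparisons use a tolerance of 10⁻⁹ × |statistic| when
  counting exceedances, so ties at the observed statistic count as hits
  (the conservative convention).
* The exhaustive/Monte-Carlo switch, iteration counts, buffer radius, rest
  speed threshold and linkage threshold are all exposed as arguments with
  the defaults above.
* Degenerate inputs error early and specifically: empty groups, constant
  vectors in rank tests, zero margins in 2×2 tables, p outside (0,1) in the
  outcome simulator, AICc with n − k − 1 ≤ 0.

## 7. Problem sizes in the test suite

The suite exercises the full pipeline at deliberately chosen scales: unit
tests run on a 6-km coarse-cell island; the cohort-level checks use the
default 12-km, 25-m island with 17 colonies and 500 simulated birds (the
scale of a multi-year tracking campaign); slope-recovery checks use 200
colonies × 50 banded birds × 100 replicate outcome draws; the grid-walk
extractor is validated against an exact crossing-midpoint oracle on 1,000
random segment/grid cases. `scripts/acceptance.R` re-runs the headline
computations from scratch under a caller-supplied seed.

## 8. Known limitations

* ESRI ASCII grid is the only raster format read or written; GeoTIFF input
  is detected and rejected with a pointer to convert.
* The walk model has no wind, no altitude dynamics coupled to behaviour,
  and a single-night horizon.
* The grounding hazard is memoryless per step; real attraction may involve
  capture dynamics (circling) that the hazard only summarises.
* Recovery probability is modelled at colony level; individual-level
  heterogeneity (body condition, fledging date) is not represented.
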