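# fallout

Flight tracks, light-pollution exposure and grounding risk of fledgling
seabirds.

## The problem

Burrow-nesting petrel fledglings leave their nests at night on their maiden
flight to the sea. Where coastlines are urbanised, many are attracted and
disoriented by artificial lights and ground inland — a mass-mortality
phenomenon known as **fallout**. Quantifying it requires stitching together
several kinds of evidence: GPS tracks of individual maiden flights, nocturnal
satellite radiance imagery, banding/recovery tables per breeding colony, and
rescue-campaign counts. `fallout` implements that entire analysis pipeline
for R, plus a synthetic island "nightscape" generator so every stage can be
exercised and tested end to end without any field data.

Intended users are movement ecologists and conservation biologists working
on light-induced seabird mortality (or any analogous point-source attraction
problem).

## What it computes

**Flight metrics.** For each track, the per-flight variables used to compare
flight groups: timing relative to apparent sunset (NOAA solar-position
algorithm, zenith 90.833°), duration, cumulative path length *L*, straight
displacement *S*, the tortuosity index

> T = 1 − S / L,  T ∈ [0, 1]  (0 = straight flight, 1 = fully convoluted),

and mean ground speed up to the first on-water rest. Distances are geodesics
on the WGS84 ellipsoid.

**Exposure extraction.** Radiance (nW sr⁻¹ cm⁻²) sampled at points, along
track polylines (exact grid-traversal of every crossed cell), and as
mean/max over a 3-km buffer of cell centres around each colony; DEM
elevation and geodesic distance to the sea; single-linkage clustering of
burrows into colonies with a 1-km chain rule.

**Inference.** Two-group randomisation tests (exhaustive enumeration when
C(n, n₁) ≤ 200,000, else Monte Carlo with the add-one convention
p = (b+1)/(m+1)); one-tailed Monte-Carlo Spearman tests (9,999
replications); Yates-corrected χ² for 2×2 tables; grouped-binomial logit
GLMs of per-colony recoveries ranked by AICc

> AICc = −2ℓ + 2k + 2k(k+1)/(n − k − 1),  n = number of colonies,

with % deviance explained and Wald CIs; variance inflation factors; and the
population back-calculation *pairs = rescued / (grounding rate × breeding
success)*.

**Synthetic nightscape.** A radial volcanic island (convex elevation
profile, 25-m DEM cells, sea as nodata) ringed by Gaussian-kernel coastal
lights clipped at 103.6 nW sr⁻¹ cm⁻²; colonies below 1,000 m elevation;
departures from a zero-truncated normal matching the observed
161.2 ± 153.8 min after sunset; flights as a biased correlated random walk
mixing directional persistence, seaward taxis (steepest DEM descent) and
phototaxis toward the brightest light within a 16-km sensing radius, with a
per-step grounding hazard proportional to radiance in excess of
18 nW sr⁻¹ cm⁻².

## Worked example

```r
library(fallout)

# a synthetic island night: terrain, coastal lights, 17 nesting colonies
scene    <- make_island(nightscape_config(seed = 2013))
colonies <- place_colonies(scene$dem, n_colonies = 17, seed = 2013)

# maiden flights of a tracked cohort, departing after apparent sunset
sunset <- apparent_sunset("2013-10-25", lon = -16.6, lat = 28.3)
cohort <- simulate_cohort(60, colonies, scene$dem, scene$radiance,
                          flight_config(seed = 2013), sunset, seed = 2013)
table(cohort$birds$outcome)
#>    grounded reached_sea
#>           3          57

flights <- summarize_cohort(cohort, colonies, sunset, scene$radiance,
                            dem = scene$dem)
round(head(flights[, c("timing_min", "duration_min", "length_m",
                       "tortuosity", "speed_kmh", "mean_radiance")], 3), 2)
#>   timing_min duration_min length_m tortuosity speed_kmh mean_radiance
#> 1      77.64          4.5  3359.25       0.01     44.79         20.89
#> 2     124.74          8.0  5971.99       0.00     44.79          0.93
#> 3      66.67          5.5  4105.73       0.00     44.79          0.25
```

Each row is one flight: the first bird left its burrow 77.6 min after
sunset, flew 3.4 km in 4.5 min at the cruise speed, essentially straight
(T = 0.01), over cells averaging 20.9 nW sr⁻¹ cm⁻² of night-light radiance.

```r
# per-colony covariates, simulated recoveries, candidate models by AICc
cov  <- colony_covariates(data.frame(colony_id = colonies$colony_id,
                                     centre_lon = colonies$lon,
                                     centre_lat = colonies$lat),
                          scene$dem, scene$radiance)
obs  <- simulate_colony_outcomes(cov, grounding_config(), n_banded = 16,
                                 seed = 2013)
fits <- lapply(c("distance_to_sea_m", "elevation_m", "radiance_mean_3km",
                 "none"), function(v) fit_binomial_logit(obs, v))
print(rank_models(fits), digits = 3)
#>           covariate estimate       se  ci_lower ci_upper aicc delta_aicc
#> 1       elevation_m  0.00571 0.000930  0.003890  0.00753 48.1       0.00
#> 2 distance_to_sea_m  0.00126 0.000225  0.000817  0.00170 50.0       1.87
#> 3 radiance_mean_3km -0.55418 0.107004 -0.763909 -0.34445 56.0       7.88
#> 4              none       NA       NA        NA       NA 92.4      44.32
```

The physical covariates (elevation, distance to sea) out-rank the light
metric, the structure the grounding-rate models are designed to expose: on
a radial island the two are strongly collinear (check `vif_table()`), which
is why only univariate candidate models are fitted.

```r
estimate_population(rescued = 863, grounding_rate = 0.14,
                    breeding_success = 0.75)
#> Population back-calculation: 863 rescued / (0.14 grounding rate x 0.75 success)
#>   = 8219.0 pairs, reported as 8200 pairs
```

A command-line wrapper is installed under `inst/cli/fallout`
(`fallout run --config run.cfg`, `fallout popsize --rescued N --rate R
--success S`); `run_all()` executes the whole pipeline from a plain-text
config and writes CSV/ASCII-grid outputs plus a JSON manifest for
reproducibility.

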