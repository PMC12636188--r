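---
title: "Estimating central-place foraging ranges of ice-associated seabirds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating central-place foraging ranges of ice-associated seabirds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icerange)
```

## The problem

Breeding seabirds are central-place foragers: every foraging trip starts
and ends at the nest, so the distance a bird can travel to feed is
bounded by the time its breeding duties allow it to be away. For
pagophilic (ice-associated) petrels nesting on inland nunataks of the
Antarctic continent, that range determines which part of the marginal
ice zone (MIZ) a colony can exploit, and hence what a biological archive
accumulated at the nest — stomach-oil deposits, guano, isotopes —
actually integrates over.

`icerange` implements the full analysis chain from raw biologging
records to projected foraging-range contours:

1. **Geolocation** (`detect_twilights()`, `estimate_positions()`,
   `screen_estimates()`): threshold light-level geolocation for archival
   loggers.
2. **Attendance** (`reduce_immersion()`, `classify_colony_days()`,
   `detect_nest_bouts()`, `infer_phenology()`): colony attendance and
   breeding phenology from wet/dry and light records.
3. **Track processing** (`split_trips()`, `regularize()`, `fit_hmm()`,
   `decode_states()`, `coast_crossings()`): GPS trip segmentation,
   state-space regularisation and 3-state behavioural classification.
4. **Space use** (`kde_ud()`, `augment_gls_locations()`,
   `autocorr_kde_ud()`, `population_ud()`, `ud_region()`): utilisation
   distributions and 50%/95% cumulative regions.
5. **Overlap** (`hroi()`, `hroi_permutation_test()`,
   `bhattacharyya()`): overlap statistics between groups.
6. **Biological distance** (`build_cost_surface()`, `distance_field()`,
   `biological_distance()`, `range_summary()`, `project_ranges()`):
   least-cost foraging-range metrics and projection.
7. **Sea ice** (`extract_ice_edge()`, `median_edge_latitude()`,
   `miz_frequency()`, `colony_edge_distance()`,
   `latitude_regression()`): ice-edge and MIZ metrics.
8. **Synthetic data** (`generate_domain()`, `generate_sic_season()`,
   `generate_tracks()`, `generate_gls_records()`,
   `generate_gps_fixes()`): a self-contained study system with known
   ground truth.

All geometry uses a spherical Earth of radius 6371.0 km and a
south-polar azimuthal equidistant projection: the study region hugs the
pole, where lon/lat grids distort badly, while the chosen projection
keeps meridional distances exact and its radial symmetry makes the
land-masked grids well behaved. Coordinates are exchanged as WGS84
decimal degrees; all times are UTC, and a "day" is the UTC calendar day.

## Threshold geolocation

Twilights are the times at which the archived maximum-light series
crosses a fixed threshold, linearly interpolated between the two
bracketing 5-min samples. Longitude places local apparent noon (or
midnight) at the midpoint of a twilight pair, with the equation of time
applied; latitude solves the day-length equation

$$\cos H = \frac{\sin a - \sin\phi\,\sin\delta}{\cos\phi\,\cos\delta}$$

for $\phi$, given the hour angle $H$ implied by the inter-twilight
interval, the solar declination $\delta$ at the midpoint, and the sun
angle $a$ — the solar elevation to which the light threshold
corresponds. Choices made where the method is conventionally
under-specified:

* **Sun angle**: calibrated per logger on a known-location (on-colony)
  period as the median true solar elevation at detected crossings;
  default $-3.5^\circ$ when uncalibrated.
* **Degeneracy flags**: latitude is refused (with a machine-readable
  reason, never silently) when $|\delta| < 0.5^\circ$ (equinox
  indeterminacy) or when the equation has no real root (polar
  day/night). Screening additionally drops estimates within ±15 days of
  an equinox — the data themselves become uninformative well before the
  algebra degenerates — estimates implying sustained speeds above
  60 km/h across gaps of ≥ 6 h, and estimates on land.
* The solar ephemeris is a low-precision Meeus-style algorithm
  (declination and equation of time from the mean anomaly and mean
  longitude), accurate to about 0.1° — an order of magnitude below the
  ~±200 km error of the method itself.

On clean synthetic light the round trip recovers a fixed site to well
under 0.5° longitude / 1° latitude away from the equinoxes; latitude
error grows without bound as the equinox approaches while longitude is
unaffected, and the tests assert exactly that contrast.

## Attendance and phenology

Wet/dry records are reduced to the wet fraction of half-open 10-min
blocks (exact integration of state-change records; total wet time is
conserved). A UTC day counts as colony attendance iff the logger was dry
strictly more than 95% of the 24 h. Nest bouts are maximal runs of
consecutive colony days on which the light sensor was shaded for at
least 70% of the day's samples — the shading criterion has no canonical
number, so 70% is a configurable default. Bouts separated by at least 5
consecutive at-sea days split pre-laying attendance from incubation
shifts; a bird still taking nest shifts after 1 January is classed as
having hatched a chick, otherwise it is considered to have failed at the
end of its last shift.

## Trip processing and the movement HMM

Trips are maximal excursions beyond a 5 km colony buffer (the buffer
radius is a convention, not an estimate), bracketed by the adjacent
in-buffer fixes and filtered by a minimum duration. Regularisation to
exact 30-min steps uses a continuous-time correlated random walk: the
velocity is an Ornstein–Uhlenbeck process and the position its integral;
mean-reversion and diffusion are estimated per trip by maximum
likelihood through a Kalman filter, and positions are predicted on the
grid by an RTS smoother. Grid times that coincide with an observed fix
return the observed position exactly; linear interpolation is available
as a documented fallback; gaps over 4 h are bridged but flagged.

Behaviour is classified with a 3-state hidden Markov model on step
lengths (gamma, parameterised by mean/sd, with an explicit per-state
point mass at zero for stationary fixes) and turning angles (von Mises;
angles undefined at duplicate positions contribute likelihood 1). Steps
are geodesic; angles are differences of successive headings on the
projected plane. The likelihood is maximised directly (scaled forward
algorithm, implemented in C++) by BFGS on log/logit/angular transforms
of the parameters, restarted from 25 random draws within configurable
plausible ranges, keeping the best likelihood; states are then
canonically relabelled by descending step mean as travel / forage /
rest. Decoding is exact Viterbi with ties broken toward the lower state
index. On well-separated 3-state simulations of 10,000 steps the fit
recovers step means within 10% and decodes ≥ 90% of states correctly;
the forward likelihood is checked exactly against brute-force path
enumeration on short sequences.

## Space use

GLS positions carry ~±200 km errors, so each estimate is augmented with
100 Gaussian draws (the km sds converted to degrees at the estimate's
latitude) before a fixed-bandwidth (default h = 100 km) Gaussian kernel
density is evaluated on a 25 km grid and renormalised. The ad-hoc
bandwidth-selection rule returns the smallest candidate h for which
every breeding stage's population 95% region has at most two 8-connected
polygons. Population utilisation distributions (UDs) are unweighted
per-cell means of individual UDs. The core foraging area and (general)
foraging area are the cells holding the first 50% and 95% of the
cumulative UD, ties at the threshold density included.

GPS foraging locations are serially autocorrelated, which makes naive
KDE too tight. The estimator here fits an exponential timescale $\tau$
to the empirical lag-correlation of the coordinates, discounts the
sample size to $N_\mathrm{eff} = N\,\Delta t/(\Delta t + 2\tau)$
(clipped to $[2, N]$), and widens the Gaussian reference-rule bandwidth
accordingly. This is a deliberate, fully-specified approximation to
autocorrelated kernel density estimation, not a re-implementation of the
ctmm estimators; its provenance label (`"gps_akde_approx"`) travels with
every UD, and UDs with different provenance refuse to be compared unless
forced — their extents are not directly comparable.

## Overlap statistics

For core areas $A_i$, $A_j$ with intersection $A_{ij}$ (cell-wise, on a
common grid),

$$HROI = \tfrac12\left(\frac{A_{ij}}{A_i} + \frac{A_{ij}}{A_j}\right)
\in [0, 1].$$

The randomisation test shuffles bird identities across the two groups
without replacement, preserving group sizes, recomputes group UDs, core
regions and HROI each time (bandwidth held at its observed value), and
reports $p$ as the proportion of null HROI values *strictly less* than
the observed value — a one-sided test of segregation in which $p = 0$ is
attainable; an optional $(B{+}1)/(N{+}1)$ correction is off by default.
A consequence of the strict rule worth knowing: when the groups are
exactly exchangeable cell-for-cell, every shuffle ties with the observed
value and the reported $p$ is 0, not 1 — ties are not "less". Under a
true null with noisy birds the test is calibrated (rejection rate at
$p<0.05$ close to nominal), which the acceptance suite verifies over 200
replicate cohorts.

Bhattacharyya's coefficient
$BC = \sum_x \sqrt{\widehat{UD}_i(x)\,\widehat{UD}_j(x)}$ is computed
without any small-sample bias correction and labelled "uncorrected".

## Biological distance

Once at sea, the birds avoid crossing land and ice shelves; overland
they commute between the colony and the coast on roughly fixed
headings. The biological distance from the colony $c$ to a location $x$
therefore combines great-circle overland legs with least-cost sea legs
through the outward and inward coast crossings $s_1$, $s_2$:

$$d_x = \tfrac12\left(d_{c,s_1} + d_{s_1,x} + d_{x,s_2} +
d_{s_2,c}\right).$$

Sea distances are single-source shortest paths over the passable-cell
graph of a rasterised cost surface (a cell is sea iff its centre is not
on land), with geodesic edge weights between cell centres. Connectivity
is 16-neighbour by default (queen plus knight moves), cutting the
worst-case planar overestimate from ~8.3% (8-neighbour) to ~2.8%; on the
sphere a small curvature correction grows with distance from the pole,
which is why the discretisation-bound checks run on pole-adjacent
grids. Origins on land snap to the nearest passable cell within 3 cells.
The shortest-path solve itself is delegated to `igraph`; the test suite
checks it exactly against an independent brute-force Dijkstra on 100
random masked grids.

Foraging range is summarised per trip (GPS, foraging locations only) or
per bird × stage (GLS, all at-sea locations) as the median ($d_{50}$),
95th percentile ($d_{95}$, linear-interpolation quantile) and maximum
($d_\mathrm{max}$) of the biological distance. For geolocator birds the
coast crossings cannot be resolved, so they are assumed at the median
crossing longitudes of GPS-tracked conspecifics
(`gls_crossing_assumption()`).

Range projection for an arbitrary colony takes $s_1$ as the first coast
intersection of the ray at the outward heading (default 317° true) and
$s_2$ from the ray at the reciprocal of the inward heading (default
173°) — field reports give the inward flight direction, not the
crossing construction, so the reciprocal-ray construction is this
package's documented choice — then contours the $d_x$ raster at the
requested distances. Contours are nested in distance by construction.

## Sea-ice metrics

The ice edge is the set of cells at or above 15% sea-ice concentration
(SIC) with a 4-neighbour below it. For edge-latitude summaries an
`outer_only` mode keeps only the most equatorward crossing per 1°
longitude bin, so that interior polynyas do not bias the median; the
climatology, by contrast, uses *all* threshold-crossing cells, as its
definition requires. The MIZ is proxied by SIC between 30% and 60%, and
`miz_frequency()` is the per-cell fraction of dates inside that closed
band. `colony_edge_distance()` averages the biological distance from a
colony to all edge cells within a 2330 km cap per day, then within
stage windows per season, then across seasons. `latitude_regression()`
is ordinary least squares of median foraging latitude on median edge
latitude, also reporting the mean meridional offset.

## The synthetic study system

The generator exists so that every stage has ground truth; its defaults
*are* the study conditions, chosen once:

* **Domain**: a zonal coastline near 70.5° S with smooth seeded wiggles
  and optional Gaussian ice-shelf promontories; one colony 190 km
  inland; 25 km cells. The sea is a single connected component.
* **Season**: the 15% edge starts near 61.5° S in October and recedes
  (smoothstep schedule, optional daily jitter) to a mid-February
  minimum; SIC ramps from 0 north of the edge through 15% at the edge
  into consolidated pack, with the 30–60% band exactly the configured
  MIZ width (200 km).
* **Calendar**: first full nest day 7 Nov, pre-laying exodus from
  18 Nov, first incubation shift 4 Dec, hatch 14 Jan, post-brood to
  mid-March; trip durations incubation 7.0 ± 2.5 d, brood-guard
  3.8 ± 0.7 d, post-brood 4.6 ± 1.2 d, drawn from truncated normals.
* **Movement**: scripted trips — overland commute out at 317° (per-trip
  von Mises jitter), at-sea transit to a target 2° of latitude south of
  the current edge, a 3-state correlated-walk foraging phase (gamma
  steps 15/3/0.3 km per 30 min; von Mises turns κ = 25/0.7/0.2;
  diagonal-dominant transition matrix) that re-targets the receding
  edge daily, and a return through the inward crossing at the
  reciprocal of 173°. Every directed leg shares the travel state's
  heading-wobble distribution: a narrower commute wobble would create a
  second, degenerate travel regime that no 3-state model could
  represent (and an exactly-constant heading makes the von Mises
  concentration diverge). At-sea positions never fall on land; the
  realised trip duration matches the drawn one to within a fix or two
  because the return leg is triggered when the remaining time first
  dips below the expected homing time.
* **Loggers**: light is a logistic transform of solar elevation at the
  interpolated position every 5 min, zeroed in the nest cavity, with
  optional multiplicative noise and shading events; immersion marks
  at-sea forage/rest states wet per 10-min block; GPS fixes sample the
  track at 30 min with optional dropout and Gaussian noise (default 0 —
  tens-of-metres GPS error is invisible at grid scale).

What the generator does *not* emulate — and what green tests therefore
do not certify about field data: real coastline topology, wind-dependent
commute costs, light-sensor weathering, device failure patterns,
individual heterogeneity beyond the drawn trip durations, and the
spatial patchiness of real pack ice. Conclusions about those require
real tracking data.

## Problem sizes and numerical choices

The shipped test and acceptance runs use a 20-bird cohort over the
exodus-to-brood-guard stages, a 25 km cost surface (the operational
3.125 km grid is supported but the coarser grid keeps the full-season
pipeline comfortable on one core; distances differ by well under the
discretisation bound), HMM fits on up to 15,000 pooled steps with 8–25
restarts, 200-replicate calibration of the permutation test at 200
shuffles, and 100 random 40 × 40 grids for the Dijkstra oracle. Other
conventions: BFGS stops at relative tolerance 1e−10 or 500 iterations;
the Kalman filter uses a 0.02 km observation sd for GPS; UD masses are
normalised to 1 within 1e−9 and region ties at the threshold density
are all included; quantiles are the linear-interpolation type; grids are
half-open with cells identified by their lower-left corner.

## Limitations

The AKDE approximation shares the intent but not the estimator of the
ctmm machinery — no confidence bands, no small-sample BC debiasing; BC
values are labelled uncorrected accordingly. GLS and GPS UDs are never
directly comparable and the package refuses to mix them silently.
Equinox-window and polar-day geolocations are dropped, not modelled.
The cost surface treats all sea (any ice concentration) as equally
passable — birds fly over pack — and ignores wind entirely.
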