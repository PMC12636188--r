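# icerange

Foraging ranges of ice-associated central-place foragers from
biologging data.

Snow petrels and other pagophilic seabirds nest up to a couple of
hundred kilometres inland on the Antarctic continent and feed in the
marginal ice zone (MIZ), commuting overland to the coast and then
tracking the seasonally receding sea-ice edge. How far a colony's birds
can range — and how that range contracts as breeding duties tighten
from the pre-laying exodus through incubation to brood-guard — decides
which ocean conditions a nest-site archive (e.g. stomach-oil deposits)
integrates, and which colonies are viable at all. `icerange` implements
the full analysis chain for this question, for users working with
archival light/immersion geolocators (GLS) and GPS loggers.

## What it computes

* **Threshold geolocation**: twilight times from max-light series,
  longitude from local noon/midnight, latitude from day length via
  `cos H = (sin a − sin φ sin δ)/(cos φ cos δ)`, with equinox/polar-day
  degeneracy flags, twilight/position filters and on-colony sun-angle
  calibration.
* **Colony attendance and phenology** from 10-min immersion blocks
  (colony day ⇔ dry > 95% of 24 h) and light shading (nest bouts,
  pre-laying exodus, hatch/failure rules).
* **Trip segmentation, CTCRW regularisation and a 3-state movement
  HMM** (gamma step lengths with an explicit zero mass, von Mises
  turning angles, 25 random restarts, Viterbi decoding) separating
  travel / forage / rest.
* **Utilisation distributions**: error-propagated fixed-bandwidth KDE
  for GLS (100 draws per position, h = 100 km), an
  autocorrelation-adjusted KDE for GPS foraging locations, population
  averaging, and 50%/95% cumulative-UD regions.
* **Overlap statistics**: the home-range overlap index
  `HROI = ½(A_ij/A_i + A_ij/A_j)` with a bird-identity randomisation
  test (p = proportion of null values strictly below the observed), and
  Bhattacharyya's coefficient `BC = Σ√(UD_i·UD_j)`.
* **Biological distance**: least-cost distance by sea over a
  land/ice-shelf-masked grid combined with great-circle overland
  commute legs through the coast crossings s1, s2:
  `d_x = (d_c,s1 + d_s1,x + d_x,s2 + d_s2,c)/2`; per-trip d50/d95/dmax
  summaries; potential-range contours projected for arbitrary colonies
  from assumed commute headings (317°/173°).
* **Sea-ice metrics**: 15% SIC ice-edge cells, sector median edge
  latitude, MIZ (30–60% SIC) frequency, colony-to-edge biological
  distance climatologies, and the regression of foraging latitude on
  edge latitude.
* **A synthetic study system** (domain, seasonal ice, tracks with known
  behavioural states, degraded logger records) providing ground truth
  for every stage.

## Worked example

Simulate a 6-bird cohort over a breeding season and run the whole
pipeline (GPS sampling → trips → HMM → biological distances → ice-edge
regression):

```r
library(icerange)
res <- run_synthetic_pipeline(seed = 2024, n_birds = 6)
res$stage_summary
#>         stage n_trips  d50_med duration_mean_d duration_drawn_mean_d
#> 1      exodus      10 716.5213       14.722917             14.724868
#> 2  incubation      16 487.0580        8.244792              8.225061
#> 3 brood_guard      15 331.2059        3.833333              3.783816
#>   forage_lat_med edge_lat_med
#> 1      -65.74651    -63.84564
#> 2      -67.99798    -65.74419
#> 3      -69.51774    -67.64423
res$offset_fit$offset_deg
#> [1] -2.009388
res$hmm$par$step_mean
#> [1] 15.0254408  3.9774602  0.2795718
res$decode_truth_agreement
#> [1] 0.9404019
```

Reading the output: the cohort's median foraging range (`d50_med`, km
of biological distance) contracts from ~720 km during the pre-laying
exodus to ~330 km during brood-guard as the ice edge recedes toward the
coast; median foraging latitude sits ~2° south of the median ice-edge
latitude in every stage (`offset_deg` ≈ −2, the value the generator
encodes); realised trip durations match the scripted draws to within a
fix interval; and the decoded HMM states agree with the generator's
true behavioural states for 94% of fixes, with the three recovered step
means (15, 4, 0.3 km per 30 min) mapping onto travel, forage and rest.

Individual stages are plain function calls — e.g. threshold geolocation
of a light series:

```r
est <- estimate_positions(
  filter_twilights(detect_twilights(light_df, threshold = 16)),
  sun_angle = -3.5)
screened <- screen_estimates(est, equinox_window_days = 15,
                             speed_limit_kmh = 60)
```

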