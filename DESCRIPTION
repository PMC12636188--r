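Package: icerange
Title: Foraging Ranges of Ice-Associated Central-Place Foragers from
    Biologging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to estimate central-place foraging ranges of polar
    seabirds from biologging records. Implements threshold light-level
    geolocation with twilight and position screening, colony-attendance
    and breeding-phenology classification from immersion loggers,
    foraging-trip segmentation and three-state hidden Markov model
    behavioural classification of GPS tracks, error-propagated and
    autocorrelation-adjusted kernel utilisation distributions with
    home-range overlap statistics (overlap index with a randomisation
    test, and Bhattacharyya's coefficient), least-cost "biological
    distance" over a land-masked sea grid, sea-ice edge and marginal
    ice zone metrics from concentration rasters, and projection of
    potential foraging-range contours for arbitrary colonies. A
    synthetic study-system generator (domain, seasonal sea ice, tracks
    with known behavioural states, degraded logger records) provides
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    igraph,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
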