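Package: shoalnet
Title: Proximity-Based Social Networks and Their Timescales from Fish Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers temporal social networks of lake fish from high-resolution
    positional telemetry using persistent spatial proximity as a proxy for
    contact, and analyses their diel and seasonal rhythms. Provides a
    correlated-random-walk trajectory simulator with tunable social attraction
    and known group structure; median-filter resampling of burst-rate fixes to
    a regular grid; pairwise distance series with bounded linear imputation;
    threshold-merge-filter contact event inference; individual (temperature,
    distance from shore, spatial entropy, speed, depth) and dyadic (interaction
    duration, inter-interaction time, interaction probability) behavioural
    indicators split by day and night; monthly aggregated networks with average
    local clustering; a whole-day time-shift null model quantifying social
    attraction as effect sizes; and a multi-timescale community-persistence
    analysis estimating the timescale of social memory via map-equation
    community detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
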