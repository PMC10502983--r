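#!/usr/bin/env Rscript
# Daily behavioural indicators, split day/night: per fish the mean
# temperature T, distance from shore d, spatial entropy S, speed v and depth
# h; per pair the mean interaction duration tau+, time between interactions
# tau- and interaction probability p; plus population averages.

library(shoalnet)
library(data.table)

out <- file.path("results", "analysis")
st <- readRDS(file.path(out, "state_preprocessed.rds"))
lake <- read_lake(file.path(out, "lake.wkt"), lat = 52.9950, lon = 13.5822)
events <- fread(file.path(out, "contact_events.csv"))
ds <- impute_gaps(pairwise_distances(st$traj))

ind <- daily_indicators(st$traj, st$diel, lake)
dyads <- dyad_stats(events, ds, st$diel)
pop_ind <- population_means(ind)
pop_dyad <- population_means(dyads)

fwrite(ind, file.path(out, "daily_indicators.csv"))
fwrite(dyads, file.path(out, "dyad_indicators.csv"))
fwrite(pop_ind, file.path(out, "population_indicators.csv"))
fwrite(pop_dyad, file.path(out, "population_dyads.csv"))

dn <- dcast(pop_ind, solar_day ~ period, value.var = "v_i")
message(sprintf(
  "Population means over %d solar days. Speed day %.2f m/s vs night %.2f m/s; interaction probability (pooled) %.3f.",
  max(pop_ind$solar_day), mean(dn$day, na.rm = TRUE), mean(dn$night, na.rm = TRUE),
  mean(pop_dyad$p_pooled, na.rm = TRUE)))
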